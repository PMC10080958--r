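test_that("noiseless piecewise-linear traces are segmented exactly", {
  t <- seq(0, 2, by = 0.02)
  az <- ifelse(t <= 1, 0 * t, 10 * (t - 1))
  el <- rep(0, length(t))
  seg <- segment_piecewise_linear(t, az, el)
  expect_equal(nrow(seg), 2)
  expect_lte(abs(seg$i0[2] - which.min(abs(t - 1))), 1)
  expect_equal(seg$velocity_dps[1], 0, tolerance = 1e-8)
  expect_equal(seg$velocity_dps[2], 10, tolerance = 1e-6)

  const <- segment_piecewise_linear(t, rep(3, length(t)), el)
  expect_equal(nrow(const), 1)
  expect_equal(const$velocity_dps, 0, tolerance = 1e-10)

  expect_error(segment_piecewise_linear(t[1:5], az[1:5], el[1:5]),
               "at least 10")
  expect_error(segment_piecewise_linear(t, rep(NA_real_, length(t)), el),
               "valid")
})

test_that("a fixation-saccade staircase is segmented at the true onsets", {
  set.seed(20)
  rate <- 50; t <- seq(0, 3.4 - 1 / rate, by = 1 / rate)
  az <- numeric(length(t)); onsets <- c()
  pos <- 0; cur <- 0
  for (k in 1:10) {
    az[t >= cur & t < cur + 0.3] <- pos
    cur <- cur + 0.3
    sel <- t >= cur & t < cur + 0.04
    az[sel] <- pos + pmin((t[sel] - cur + 0.01) / 0.04, 1) * 2
    onsets <- c(onsets, cur)
    cur <- cur + 0.04; pos <- pos + 2
  }
  az[t >= cur] <- pos
  azn <- az + rnorm(length(t), 0, 0.1)
  el <- rnorm(length(t), 0, 0.1)
  seg <- segment_piecewise_linear(t, azn, el)
  expect_gte(nrow(seg), 11)   # >= 10 breakpoints
  for (on in onsets) {
    i_true <- which.min(abs(t - on))
    expect_lte(min(abs(seg$i0 - i_true)), 1)
  }
})

test_that("velocity priors dominate state assignment", {
  mkseg <- function(v, dur = 0.2) {
    # one slow reference segment followed by the probe segment
    t <- seq(0, 0.4 + dur, by = 0.02)
    az <- ifelse(t <= 0.4, 0.01 * t, 0.01 * 0.4 + v * (t - 0.4))
    segment_piecewise_linear(t, az, rep(0, length(t)),
                             classifier_config(saccade_seed_dps = 1e9))
  }
  cls <- function(v, dur = 0.2) {
    iv <- classify_segments(mkseg(v, dur))
    iv$label[nrow(iv)]
  }
  expect_equal(cls(0.5), "fixation")
  expect_equal(cls(300, 0.06), "saccade")
  expect_equal(cls(10, 0.5), "smooth_pursuit")
})

test_that("PSO never occurs without an immediately preceding saccade", {
  for (which in c("reading", "walking")) {
    iv <- acc_intervals(which)
    pso <- which(iv$label == "pso")
    for (k in pso) {
      expect_gt(k, 1)
      expect_equal(iv$label[k - 1], "saccade")
      expect_equal(iv$chunk[k - 1], iv$chunk[k])
    }
    sac_after_pso <- which(iv$label == "saccade" &
                             c("", iv$label[-nrow(iv)]) == "pso" &
                             c(-1, iv$chunk[-nrow(iv)]) == iv$chunk)
    expect_length(sac_after_pso, 0)
  }
})

test_that("intervals tile each chunk without overlap", {
  iv <- acc_intervals("walking")
  expect_true(all(iv$end_s > iv$start_s))
  same_chunk <- iv$chunk[-nrow(iv)] == iv$chunk[-1]
  expect_equal(iv$end_s[-nrow(iv)][same_chunk],
               iv$start_s[-1][same_chunk])
})

test_that("classification is deterministic", {
  sim <- tiny_reading()
  a <- classify_eye_movements(sim$session)
  b <- classify_eye_movements(sim$session)
  expect_identical(a, b)
})

test_that("saccade metrics follow the Euclidean amplitude definition", {
  iv <- data.frame(label = "saccade", start_s = 0, end_s = 0.02,
                   mean_velocity_dps = 0, amplitude_deg = 0,
                   i0 = 1L, i1 = 2L, chunk = 1L)
  m <- saccade_metrics(iv, azimuth = c(0, 3), elevation = c(0, 4))
  expect_equal(m$amplitude_deg, 5)
  expect_equal(m$velocity_dps, 250)
  m2 <- saccade_metrics(iv, azimuth = c(0, 0), elevation = c(0, 0))
  expect_equal(m2$amplitude_deg, 0)
  iv$end_s <- 0.01
  m3 <- saccade_metrics(iv, azimuth = c(0, 2), elevation = c(0, 0))
  expect_equal(m3$velocity_dps, 200)
  iv$end_s <- 0
  expect_error(saccade_metrics(iv, azimuth = c(0, 2),
                               elevation = c(0, 0)), "zero-duration")
})

test_that("fixation metrics include smooth pursuit", {
  iv <- data.frame(label = c("fixation", "saccade", "smooth_pursuit"),
                   start_s = c(0, 0.22, 0.26), end_s = c(0.22, 0.26, 0.76),
                   mean_velocity_dps = c(1, 100, 8),
                   amplitude_deg = c(0.1, 2, 4),
                   i0 = c(1L, 12L, 14L), i1 = c(11L, 13L, 38L),
                   chunk = 1L)
  fm <- fixation_metrics(iv)
  expect_equal(fm$count, 2)
  expect_equal(fm$durations_s, c(0.22, 0.5))
  expect_equal(fixation_metrics(iv[0, ])$count, 0)
  expect_length(fixation_metrics(iv[0, ])$durations_s, 0)
})
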