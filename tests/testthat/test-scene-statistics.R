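# naive two-pass loop oracles, deliberately independent of the package code
oracle_contrast <- function(L, axis) {
  if (axis == "space") {
    vapply(seq_len(ncol(L)), function(t) {
      v <- L[, t]; v <- v[is.finite(v)]
      if (length(v) < 2) return(NA_real_)
      mu <- 0; for (x in v) mu <- mu + x; mu <- mu / length(v)
      ss <- 0; for (x in v) ss <- ss + (x - mu)^2
      sqrt(ss / (length(v) - 1))
    }, numeric(1))
  } else {
    oracle_contrast(t(L), "space")
  }
}

oracle_skewness <- function(L, axis) {
  if (axis == "space") {
    vapply(seq_len(ncol(L)), function(t) {
      v <- L[, t]; v <- v[is.finite(v)]
      if (length(v) < 2) return(NA_real_)
      mu <- mean(v)
      C <- sqrt(sum((v - mu)^2) / (length(v) - 1))
      if (C == 0) return(NA_real_)
      s <- 0; for (x in v) s <- s + ((x - mu) / C)^3
      s / length(v)
    }, numeric(1))
  } else {
    oracle_skewness(t(L), "space")
  }
}

test_that("worked four-pixel examples hold exactly", {
  expect_identical(rms_contrast(matrix(c(0, 0, 0, 1)), "space")[[1]], 0.5)
  expect_identical(luminance_skewness(matrix(c(0, 0, 0, 1)), "space")[[1]],
                   0.75)
  expect_identical(luminance_skewness(matrix(c(1, 1, 1, 0)), "space")[[1]],
                   -0.75)
  expect_equal(luminance_skewness(matrix(c(0, 1, 0, 1)), "space")[[1]], 0)
  expect_equal(rms_contrast(matrix(rep(0.3, 4)), "space")[[1]], 0)
  # half ones / half zeros closed form
  v <- c(rep(1, 500), rep(0, 500))
  expect_equal(rms_contrast(matrix(v), "space")[[1]],
               sqrt(500 * 500 / (1000 * 999)), tolerance = 1e-12)
  expect_equal(rms_contrast(matrix(v), "space")[[1]], 0.50025,
               tolerance = 1e-5)
})

test_that("contrast and skewness match the loop oracle with missing data", {
  set.seed(10)
  for (rep in 1:8) {
    L <- matrix(runif(20 * 30), 20, 30)
    L[sample(length(L), 60)] <- NA
    lm <- list(L = L, valid = is.finite(L), n_s = 20, n_t = 30)
    class(lm) <- "luminance_matrix"
    for (axis in c("space", "time")) {
      expect_equal(as.numeric(rms_contrast(lm, axis)),
                   oracle_contrast(L, axis), tolerance = 1e-12)
      expect_equal(as.numeric(luminance_skewness(lm, axis)),
                   oracle_skewness(L, axis), tolerance = 1e-12)
    }
  }
})

test_that("contrast/skewness invariances: shift, scale, polarity", {
  set.seed(11)
  L <- matrix(runif(50 * 20, 0.2, 0.6), 50, 20)
  c0 <- rms_contrast(L, "space"); s0 <- luminance_skewness(L, "space")
  expect_equal(rms_contrast(L + 0.2, "space"), c0, tolerance = 1e-12)
  expect_equal(luminance_skewness(L + 0.2, "space"), s0, tolerance = 1e-12)
  expect_equal(rms_contrast(L * 1.5, "space"), 1.5 * c0, tolerance = 1e-12)
  expect_equal(luminance_skewness(L * 1.5, "space"), s0, tolerance = 1e-12)
  # polarity inversion about the column means flips the skewness sign
  mu <- matrix(colMeans(L), nrow(L), ncol(L), byrow = TRUE)
  expect_equal(luminance_skewness(2 * mu - L, "space"), -s0,
               tolerance = 1e-12)
})

test_that("mean pixel intensity averages valid cells", {
  expect_equal(mean_pixel_intensity(matrix(1, 4, 4))$grand_mean, 1)
  expect_equal(mean_pixel_intensity(matrix(c(1, 1, 0, 0), 4, 2))$grand_mean,
               0.5)
  expect_equal(mean_pixel_intensity(matrix(c(0.2, 0.4, 0.6)))$grand_mean,
               0.4)
  mp <- mean_pixel_intensity(matrix(c(0.2, NA, 0.6, 0.8), 2, 2))
  expect_equal(mp$per_frame, c(0.2, 0.7))
})

test_that("average power spectrum localizes energy correctly", {
  cam <- camera_model(scene_fov_deg = c(8, 8),
                      scene_resolution_px = c(64, 64))
  # constant frames: everything in the lowest bins (window leakage only)
  frames <- array(128, c(64, 64, 3))
  sp <- average_power_spectrum(frames, cam)
  p <- 10^sp$log10_power
  expect_gt(sum(p[sp$freq_cdeg < 0.3]) / sum(p), 1 - 1e-12)
  expect_true(!is.unsorted(sp$freq_cdeg))
  expect_true(all(sp$freq_cdeg <= 4))    # Nyquist = 8 ppd / 2

  # grating at 1 cycle/deg peaks at 1 cycle/deg
  x <- outer(rep(1, 64), 0:63)
  g <- array(127.5 + 127 * sin(2 * pi * 8 * x / 64), c(64, 64, 2))
  spg <- average_power_spectrum(g, cam)
  nz <- spg$freq_cdeg > 0.3
  expect_equal(spg$freq_cdeg[nz][which.max(spg$log10_power[nz])], 1,
               tolerance = 0.06)

  # white noise is flat: log-log slope near zero
  set.seed(12)
  wn <- array(runif(64 * 64 * 40, 0, 255), c(64, 64, 40))
  spw <- average_power_spectrum(wn, cam)
  sel <- spw$freq_cdeg > 0.2 & spw$freq_cdeg < 3.5
  fit <- stats::lm(spw$log10_power[sel] ~ log10(spw$freq_cdeg[sel]))
  expect_lt(abs(unname(stats::coef(fit)[2])), 0.1)
})

test_that("half-range eccentricity interpolates the first crossing", {
  d <- seq(5, 60, length.out = 12)
  expect_equal(half_range_eccentricity(d, (d - 5) / 55), 32.5)
  d2 <- c(5, 10, 15, 20, 25, 30, 60)
  v2 <- c(0, 0, 0, 1, 1, 1, 1)
  expect_equal(half_range_eccentricity(d2, v2), 17.5)
  expect_warning(out <- half_range_eccentricity(d2, rep(1, 7)), "undefined")
  expect_true(is.na(out))
  expect_error(half_range_eccentricity(c(5, 10), c(0, 1)))
})

test_that("retinal illuminance reproduces the printed worked values", {
  expect_equal(retinal_illuminance_trolands(2, 4.24), 28.22,
               tolerance = 0.01)
  expect_equal(retinal_illuminance_trolands(90, 3.70), 965.94,
               tolerance = 0.01)
  expect_equal(retinal_illuminance_trolands(9500, 2.09), 32484.11,
               tolerance = 0.01)
  # unit pupil area: T equals L
  expect_equal(retinal_illuminance_trolands(37, 2 / sqrt(pi)), 37,
               tolerance = 1e-12)
  expect_error(retinal_illuminance_trolands(-1, 3), "positive")
  expect_error(retinal_illuminance_trolands(10, 0), "positive")
})

test_that("gaussian fit recovers parameters", {
  x <- seq(-4, 4, length.out = 60)
  y <- 0 + 1 * exp(-x^2 / 2)
  f <- fit_gaussian(x, y)
  expect_equal(f$b, 0, tolerance = 1e-6)
  expect_equal(f$a, 1, tolerance = 1e-6)
  expect_equal(f$mu, 0, tolerance = 1e-6)
  expect_equal(f$sigma, 1, tolerance = 1e-6)
  expect_gt(f$r2, 1 - 1e-10)
  # peak identity y(mu) = b + a
  y2 <- 0.3 + 2 * exp(-(x - 0.7)^2 / (2 * 0.5^2))
  f2 <- fit_gaussian(x, y2)
  expect_equal(f2$b + f2$a, 0.3 + 2, tolerance = 1e-5)
  # small noise: parameters within 5% of truth
  set.seed(13)
  y3 <- y2 + rnorm(length(x), 0, 0.01)
  f3 <- fit_gaussian(seq(-4, 4, length.out = 60), y3)
  expect_equal(f3$a, 2, tolerance = 0.05)
  expect_equal(f3$mu, 0.7, tolerance = 0.05)
  expect_equal(f3$sigma, 0.5, tolerance = 0.05)
})

test_that("alpha fit recovers parameters and peak identity", {
  x <- seq(0, 3, length.out = 80)
  curve <- function(x, b, d, r, a) {
    z <- (x - a) / r
    pmax(0, b + d * z * exp(1 - z))
  }
  y <- curve(x, 0, 1, 0.5, 0.1)
  f <- fit_alpha(x, y)
  expect_equal(f$b, 0, tolerance = 1e-4)
  expect_equal(f$d, 1, tolerance = 1e-4)
  expect_equal(f$r, 0.5, tolerance = 1e-4)
  expect_equal(f$a, 0.1, tolerance = 1e-4)
  # peak at x = a + r with value b + d; y(a) = max(0, b)
  expect_equal(curve(0.1 + 0.5, 0.2, 1.3, 0.5, 0.1), 0.2 + 1.3)
  expect_equal(curve(0.1, 0.2, 1.3, 0.5, 0.1), 0.2)
  grid <- seq(0, 3, by = 1e-4)
  expect_equal(grid[which.max(curve(grid, 0.2, 1.3, 0.5, 0.1))], 0.6,
               tolerance = 1e-3)
})
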