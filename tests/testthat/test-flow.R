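test_that("polynomial expansion recovers an exact quadratic surface", {
  A <- matrix(c(0.02, 0.01, 0.01, -0.03), 2)
  b <- c(0.5, -0.2); cc <- 3
  img <- outer(1:40, 1:50, function(i, j)
    A[1, 1] * j^2 + A[2, 2] * i^2 + 2 * A[1, 2] * i * j +
      b[1] * j + b[2] * i + cc)
  pe <- polynomial_expansion(img)
  for (p in list(c(10, 10), c(20, 25), c(35, 40))) {
    i <- p[1]; j <- p[2]
    expect_equal(pe$axx[i, j], A[1, 1], tolerance = 1e-9)
    expect_equal(pe$ayy[i, j], A[2, 2], tolerance = 1e-9)
    expect_equal(pe$axy[i, j], A[1, 2], tolerance = 1e-9)
    expect_equal(pe$bx[i, j], 2 * A[1, 1] * j + 2 * A[1, 2] * i + b[1],
                 tolerance = 1e-9)
    expect_equal(pe$by[i, j], 2 * A[2, 2] * i + 2 * A[1, 2] * j + b[2],
                 tolerance = 1e-9)
    expect_equal(pe$c[i, j], img[i, j], tolerance = 1e-8)
  }
})

test_that("identical frames give a (near) zero field", {
  tex <- smooth_texture(80, 100, seed = 50)
  fl <- polynomial_expansion_flow(tex, tex)
  expect_lt(max(abs(fl$dx)), 0.05)
  expect_lt(max(abs(fl$dy)), 0.05)
  expect_error(polynomial_expansion_flow(tex, tex[1:40, ]), "identical size")
  expect_error(polynomial_expansion_flow(tex[1:4, 1:4], tex[1:4, 1:4]),
               "too small")
})

test_that("integer translations are recovered", {
  tex <- smooth_texture(200, 320, seed = 51)
  a <- tex[, 21:300]
  b <- tex[, 18:297]             # content shifted 3 px rightward
  fl <- polynomial_expansion_flow(a, b)
  expect_equal(mean(fl$dx), 3, tolerance = 0.25)
  expect_lt(abs(mean(fl$dy)), 0.2)
  # reverse order gives (approximately) the negated field
  flr <- polynomial_expansion_flow(b, a)
  expect_lt(abs(mean(fl$dx + flr$dx)), 0.1)
})

test_that("sub-pixel translation error is below 0.2 px", {
  # analytic smooth texture sampled on shifted grids
  f <- function(x, y) {
    127 + 50 * sin(2 * pi * x / 37) * cos(2 * pi * y / 29) +
      40 * sin(2 * pi * (x + y) / 53) + 30 * cos(2 * pi * x / 17)
  }
  grid <- expand.grid(y = 1:120, x = 1:160)
  a <- matrix(f(grid$x, grid$y), 120, 160)
  b <- matrix(f(grid$x - 0.5, grid$y), 120, 160)
  fl <- polynomial_expansion_flow(a, b)
  inner <- fl$dx[20:100, 20:140]
  expect_lt(mean(abs(inner - 0.5)), 0.2)
})

test_that("average horizontal flow tracks global pans with sign", {
  tex <- smooth_texture(60, 220, seed = 52)
  static <- array(0, c(60, 160, 4))
  for (i in 1:4) static[, , i] <- tex[, 31:190]
  tr <- average_horizontal_flow(static)
  expect_lt(max(abs(tr$mean_dx_px)), 0.05)

  pan <- array(0, c(60, 160, 5))
  for (i in 1:5) pan[, , i] <- tex[, (31 - 3 * (i - 1)):(190 - 3 * (i - 1))]
  trp <- average_horizontal_flow(pan)
  expect_true(all(abs(trp$mean_dx_px - 3) < 0.4))

  panl <- array(0, c(60, 160, 4))
  for (i in 1:4) panl[, , i] <- tex[, (31 + 3 * (i - 1)):(190 + 3 * (i - 1))]
  trl <- average_horizontal_flow(panl)
  expect_true(all(trl$mean_dx_px < -2))
  expect_error(average_horizontal_flow(static[, , 1, drop = FALSE]),
               "at least 2")
})

test_that("flow peaks respect threshold, separation, and tail exclusion", {
  t <- seq(0, 40, by = 0.04)
  mk <- function(centers, amp = 10, width = 0.5) {
    x <- rep(0, length(t))
    for (ctr in centers) x <- x + amp * exp(-(t - ctr)^2 / (2 * width^2))
    data.frame(t = t, mean_dx_px = x)
  }
  p1 <- detect_flow_peaks(mk(15))
  expect_equal(nrow(p1), 1)
  expect_lt(abs(p1$peak_t - 15), 0.2)
  # a bump entirely inside the final 10 s is excluded
  expect_equal(nrow(detect_flow_peaks(mk(36))), 0)
  # everything below 20% of the reference maximum
  low <- mk(15, amp = 1)
  expect_equal(nrow(detect_flow_peaks(low, reference_max = 10)), 0)
  # negative-going peaks count via the absolute trace
  neg <- mk(15); neg$mean_dx_px <- -neg$mean_dx_px
  expect_equal(nrow(detect_flow_peaks(neg)), 1)
  # peaks closer than the separation collapse to the larger one
  two <- mk(c(15, 15.3))
  expect_equal(nrow(detect_flow_peaks(two)), 1)
})

test_that("OKN segment extraction enforces window and validity rules", {
  rate <- 50
  t <- seq(0, 60 - 1 / rate, by = 1 / rate)
  eye <- sin(2 * pi * 3 * t)
  segs <- extract_okn_segments(t, eye, 30)
  expect_length(segs, 1)
  expect_length(segs[[1]]$samples, 100)
  expect_equal(segs[[1]]$n_valid, 100)
  # fewer than 60 valid samples: rejected
  mask <- rep(FALSE, length(t)); mask[t > 29.2 & t < 30.2] <- TRUE
  expect_length(extract_okn_segments(t, eye, 30, blink_mask = mask), 0)
  # 30 invalid of 100 is acceptable; invalid samples are interpolated
  mask2 <- rep(FALSE, length(t)); mask2[t > 29.7 & t < 30.2] <- TRUE
  segs2 <- extract_okn_segments(t, eye, 30, blink_mask = mask2)
  expect_length(segs2, 1)
  expect_true(all(is.finite(segs2[[1]]$samples)))
  # window extending beyond the recording: rejected
  expect_length(extract_okn_segments(t, eye, 0.5), 0)
  expect_length(extract_okn_segments(t, eye, 59.8), 0)
})

test_that("OKN spectral metrics find the in-band dominant frequency", {
  rate <- 50
  tt <- (0:99) / rate
  s3 <- okn_amplitude_frequency(sin(2 * pi * 3 * tt), rate_hz = rate)
  expect_equal(s3$freq_hz, 3)
  expect_false(s3$low_confidence)
  mix <- 0.5 * sin(2 * pi * 2.5 * tt) + sin(2 * pi * 5 * tt)
  expect_equal(okn_amplitude_frequency(mix, rate_hz = rate)$freq_hz, 5)
  slow <- okn_amplitude_frequency(sin(2 * pi * 1 * tt), rate_hz = rate)
  expect_true(slow$low_confidence)
})
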