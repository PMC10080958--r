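test_that("save/load round trip is lossless", {
  sim <- constant_session(seconds = 2)
  # overwrite with non-trivial frames so the test is not vacuous
  set.seed(5)
  sim$scene_frames[] <- as.raw(sample(0:255, length(sim$scene_frames),
                                      replace = TRUE))
  dir <- withr::local_tempdir()
  save_session(sim, dir)
  back <- load_session(dir)
  expect_identical(back$scene_frames, sim$scene_frames)
  expect_identical(back$eye_frames, sim$eye_frames)
  expect_equal(back$gaze$t, sim$gaze$t, tolerance = 0)
  expect_equal(back$gaze$gp, sim$gaze$gp, tolerance = 0,
               ignore_attr = TRUE)
  expect_equal(back$gaze$gp3, sim$gaze$gp3, tolerance = 0,
               ignore_attr = TRUE)
  expect_equal(back$gaze$pd_left, sim$gaze$pd_left, tolerance = 0)
  expect_identical(back$gaze$validity, sim$gaze$validity)
  expect_equal(back$imu$gy, sim$imu$gy, tolerance = 0, ignore_attr = TRUE)
  expect_equal(back$imu$ac, sim$imu$ac, tolerance = 0, ignore_attr = TRUE)
  expect_identical(back$task_label, sim$task_label)
})

test_that("missing streams produce named errors", {
  sim <- constant_session(seconds = 2)
  dir <- withr::local_tempdir()
  save_session(sim, dir)
  # drop the imu records from the stream file
  lines <- readLines(file.path(dir, "livedata.json"))
  writeLines(lines[!grepl('"ac"|"gy"', lines)],
             file.path(dir, "livedata.json"))
  expect_error(load_session(dir), "imu stream missing")

  dir2 <- withr::local_tempdir()
  save_session(sim, dir2)
  unlink(file.path(dir2, "scene"), recursive = TRUE)
  expect_error(load_session(dir2), "scene stream missing")
  expect_error(load_session(file.path(dir2, "nope")), "not found")
})

test_that("timestamp monotonicity is enforced with the offending index", {
  t <- c(0, 0.02, 0.015, 0.06)
  expect_error(gaze_stream(t, matrix(0.5, 4, 2), matrix(c(0, 0, 500), 4, 3,
                                                        byrow = TRUE)),
               "index 3")
})

test_that("synthetic session frame and sample counts follow the rates", {
  sim <- simulate_reading_session(reading_config(duration_s = 30,
                                                 scene_px = c(160, 90)),
                                  seed = 55)
  s <- sim$session
  expect_lte(abs(dim(s$scene_frames)[3] - 750), 1)
  expect_lte(abs(dim(s$eye_frames)[3] - 1500), 1)
  expect_lte(abs(length(s$imu$t) - 3000), 1)
  expect_lte(abs(length(s$gaze$t) - 1500), 1)
  expect_silent(validate_session(s))
})

test_that("gaze_to_degrees matches hand calculations and is odd", {
  expect_equal(unname(gaze_to_degrees(c(0, 0, 500))), c(0, 0))
  expect_equal(unname(gaze_to_degrees(c(100, 0, 1000))[1]),
               atan(0.1) * 180 / pi, tolerance = 1e-10)
  expect_equal(unname(gaze_to_degrees(c(100, 0, 1000))[1]), 5.71,
               tolerance = 1e-3)
  expect_equal(unname(gaze_to_degrees(c(0, -100, 1000))),
               c(0, -5.71), tolerance = 1e-3)
  # odd in the image-plane arguments
  set.seed(2)
  for (i in 1:20) {
    v <- c(runif(2, -300, 300), runif(1, 100, 2000))
    expect_equal(unname(gaze_to_degrees(c(-v[1], -v[2], v[3]))),
                 -unname(gaze_to_degrees(v)), tolerance = 1e-12)
  }
  # non-positive depth flags the sample instead of erroring
  expect_true(all(is.na(gaze_to_degrees(c(10, 10, 0)))))
  expect_true(all(is.na(gaze_to_degrees(c(10, 10, -5)))))
})

test_that("luminance_image implements the BT.601 weighted sum", {
  mk <- function(r, g, b) {
    px <- array(0, c(1, 1, 3)); px[1, 1, ] <- c(r, g, b); px
  }
  expect_equal(luminance_image(mk(255, 255, 255))[1, 1], 255L)
  expect_equal(luminance_image(mk(0, 0, 0))[1, 1], 0L)
  expect_equal(luminance_image(mk(255, 0, 0))[1, 1], 76L)
  # gray inputs map to themselves exactly
  for (v in c(0L, 1L, 17L, 128L, 200L, 254L, 255L))
    expect_identical(luminance_image(mk(v, v, v))[1, 1], v)
  expect_error(luminance_image(array(0, c(2, 2, 4))), "3-channel")
  expect_error(luminance_image(matrix(0, 2, 2)), "3-channel")
})

test_that("pixels_per_degree reproduces the printed sampling densities", {
  cam <- camera_model()
  expect_equal(round(pixels_per_degree(cam, "horizontal")), 23)
  expect_equal(round(pixels_per_degree(cam, "vertical")), 21)
  expect_equal(pixels_per_degree(cam, "horizontal"), 1920 / 82)
  toy <- camera_model(scene_fov_deg = c(10, 10),
                      scene_resolution_px = c(100, 100))
  expect_equal(pixels_per_degree(toy, "horizontal"), 10)
  expect_error(camera_model(scene_rate_hz = 0), "rates")
})
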