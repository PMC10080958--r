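test_that("generators are deterministic under a fixed seed", {
  a <- simulate_reading_session(reading_config(duration_s = 4,
                                               scene_px = c(160, 90)),
                                seed = 60)
  b <- simulate_reading_session(reading_config(duration_s = 4,
                                               scene_px = c(160, 90)),
                                seed = 60)
  expect_identical(a$session$gaze, b$session$gaze)
  expect_identical(a$session$scene_frames[, , 1], b$session$scene_frames[, , 1])
  expect_identical(a$truth$labels, b$truth$labels)
  cc <- simulate_reading_session(reading_config(duration_s = 4,
                                                scene_px = c(160, 90)),
                                 seed = 61)
  expect_false(identical(a$session$gaze$gp, cc$session$gaze$gp))
})

test_that("invalid configurations are rejected", {
  expect_error(simulate_reading_session(
    reading_config(viewing_distance_m = 8)), "fovea")
  expect_error(simulate_walking_session(
    walking_config(duration_s = 20, turn_times_s = c(19),
                   turn_dirs = 1)), "turn schedule")
  expect_error(simulate_walking_session(
    walking_config(turn_times_s = c(10, 20), turn_dirs = 1)), "turn_dirs")
})

test_that("reading fixation durations match the configured distribution", {
  sim <- acc_reading()
  fix <- Filter(function(e) e$type == "fixation", sim$truth$events)
  dur <- vapply(fix, function(e) e$t1 - e$t0, numeric(1))
  expect_gte(length(dur), 200)
  expect_lt(abs(mean(dur) - 0.22) / 0.22, 0.1)
})

test_that("foveal luminance during reading is bimodal (page vs ink)", {
  sim <- tiny_reading()
  iv <- data.frame(label = "fixation", start_s = 0,
                   end_s = sim$session$duration_s)
  offs <- draw_region_offsets(retinal_region("fovea"), 800, seed = 62)
  L <- gaze_centered_luminance(sim$session, offs, iv)
  v <- L$L[L$valid]
  expect_gt(mean(v > 0.8), 0.5)     # mostly page white
  expect_gt(mean(v < 0.75), 0.05)   # a solid minority of darkened ink
})

test_that("walking scenes carry the scheduled turn flow and luminance bands", {
  sim <- tiny_walking()
  expect_equal(sim$truth$turn_times_s, 5 + 2.5 / 2)
  fl <- average_horizontal_flow(sim$session)
  peaks <- detect_flow_peaks(fl, exclude_tail_s = 5)
  expect_gte(nrow(peaks), 1)
  expect_lt(min(abs(peaks$peak_t - sim$truth$turn_times_s)), 1)
  # the largest |flow| occurs inside the turn
  imax <- which.max(abs(fl$mean_dx_px))
  expect_true(fl$t[imax] > 5 && fl$t[imax] < 7.5)
  # luminance mapping: fixed white point recorded in the ground truth
  expect_equal(unname(sim$truth$lum_mapping["white_point_cdm2"]), 250)
})

test_that("synthetic sessions validate and round-trip through session IO", {
  sim <- simulate_reading_session(reading_config(duration_s = 3,
                                                 scene_px = c(160, 90)),
                                  seed = 63)
  expect_silent(validate_session(sim$session))
  dir <- withr::local_tempdir()
  save_session(sim$session, dir)
  save_ground_truth(sim$truth, dir)
  back <- load_session(dir)
  expect_equal(back$gaze$gp, sim$session$gaze$gp, tolerance = 0,
               ignore_attr = TRUE)
  expect_identical(back$scene_frames, sim$session$scene_frames)
  truth_csv <- utils::read.csv(file.path(dir, "truth.csv"))
  expect_equal(nrow(truth_csv), nrow(sim$truth$labels))
  meta <- jsonlite::fromJSON(readLines(file.path(dir, "truth.json")))
  expect_equal(meta$lum_mapping$white_point_cdm2, 100)
})

test_that("ground truth labels every gaze sample", {
  for (sim in list(tiny_reading(), tiny_walking())) {
    expect_equal(nrow(sim$truth$labels), length(sim$session$gaze$t))
    expect_true(all(sim$truth$labels$label %in%
                      c("fixation", "saccade", "smooth_pursuit")))
  }
})
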