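# Session fixtures are generated in code and cached for the test run.
# The "acc_" sessions are the acceptance-scale worlds (60 s, 480x270,
# fixed seeds); the "tiny_" sessions keep unit tests fast.

.session_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .session_cache))
    assign(key, force(expr), envir = .session_cache)
  get(key, envir = .session_cache)
}

tiny_reading <- function()
  cached("tiny_reading",
         simulate_reading_session(reading_config(duration_s = 10,
                                                 scene_px = c(160, 90)),
                                  seed = 101))

tiny_walking <- function()
  cached("tiny_walking",
         simulate_walking_session(walking_config(duration_s = 20,
                                                 turn_times_s = 5,
                                                 turn_dirs = 1,
                                                 scene_px = c(160, 90)),
                                  seed = 102))

acc_reading <- function()
  cached("acc_reading", simulate_reading_session(reading_config(), seed = 1))

acc_walking <- function()
  cached("acc_walking", simulate_walking_session(walking_config(), seed = 2))

acc_intervals <- function(which) {
  key <- paste0("iv_", which)
  sim <- if (which == "reading") acc_reading() else acc_walking()
  cached(key, classify_eye_movements(sim$session))
}

acc_region_stats <- function(which) {
  key <- paste0("stats_", which)
  cached(key, {
    sim <- if (which == "reading") acc_reading() else acc_walking()
    iv <- acc_intervals(which)
    fov <- draw_region_offsets(retinal_region("fovea"), 1000, seed = 11)
    per <- draw_region_offsets(retinal_region("periphery"), 1000, seed = 12)
    list(fovea = spatio_temporal_stats(
           gaze_centered_luminance(sim$session, fov, iv)),
         periphery = spatio_temporal_stats(
           gaze_centered_luminance(sim$session, per, iv)))
  })
}

finite_mean <- function(x) mean(x[is.finite(x)])

# a constant-luminance session: white frames, centred steady gaze
constant_session <- function(value = 255, seconds = 3) {
  cam <- camera_model(scene_fov_deg = c(40, 30),
                      scene_resolution_px = c(80, 60),
                      eye_resolution_px = c(16, 16))
  n_scene <- seconds * 25
  scene <- array(as.raw(value), c(60, 80, n_scene))
  eyes <- array(as.raw(128), c(16, 16, seconds * 50))
  t50 <- (seq_len(seconds * 50) - 1) / 50
  set.seed(99)
  az <- rnorm(length(t50), 0, 0.05)
  el <- rnorm(length(t50), 0, 0.05)
  gp <- cbind(0.5 + az / 40, 0.5 + el / 30)
  gp3 <- cbind(tan(az * pi / 180) * 500, tan(el * pi / 180) * 500, 500)
  gaze <- gaze_stream(t50, gp, gp3, pd_left = rep(4, length(t50)),
                      pd_right = rep(4, length(t50)))
  t100 <- (seq_len(seconds * 100) - 1) / 100
  imu <- imu_stream(t100, matrix(0, length(t100), 3),
                    matrix(rnorm(length(t100) * 3, 0, 0.5), ncol = 3))
  session_bundle(cam, scene, eyes, gaze, imu, task_label = "constant")
}

# smooth random texture for optical-flow tests (circularly smoothed noise)
smooth_texture <- function(h, w, seed = 1, k = 7) {
  set.seed(seed)
  m <- matrix(rnorm(h * w), h, w)
  sm1 <- function(x) {
    out <- apply(x, 2, function(col)
      as.numeric(stats::filter(col, rep(1 / k, k), circular = TRUE)))
    t(apply(t(out), 2, function(r)
      as.numeric(stats::filter(r, rep(1 / k, k), circular = TRUE))))
  }
  m <- sm1(sm1(m))
  (m - min(m)) / (max(m) - min(m)) * 255
}
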