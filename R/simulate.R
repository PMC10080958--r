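#' Reading-session simulator configuration
#'
#' The stated world of the reading task: a 25.5 x 26 cm text page viewed at
#' 0.5 m on a computer screen (page ~29 x 29 degrees), dark text
#' (2 cd/m^2) on a white page (90 cd/m^2) over a dim office surround,
#' left-to-right line-scanning saccades with return sweeps, fixation
#' durations of 0.22 +/- 0.15 s, a low blink rate, and a nearly stationary
#' head. Text is rendered as glyph-like stroke runs at the device's native
#' resolution and area-downsampled to the working frame size, which
#' reproduces the partial-pixel "ink" grays a real scene camera records
#' for 0.4 cm letters.
#'
#' @param duration_s session length.
#' @param page_size_cm page width and height.
#' @param font_height_cm glyph height.
#' @param viewing_distance_m eye-to-page distance.
#' @param background_cdm2,text_cdm2 page and ink luminances (swap for
#'   white-on-black reading).
#' @param surround_cdm2 luminance of the scene outside the page.
#' @param fixation_mean_s,fixation_sd_s fixation duration distribution.
#' @param saccade_deg forward reading saccade amplitude.
#' @param blink_rate_per_min blink rate.
#' @param blink_mean_frames mean blink duration in 50 Hz frames.
#' @param pupil_mm mean pupil diameter.
#' @param gaze_noise_deg per-sample gaze noise RMS.
#' @param ink_coverage target ink fraction within text lines (0.10-0.15).
#' @param camera_psf_px Gaussian sd (native pixels) of the scene camera's
#'   optical point spread; softens sub-stroke text the way a small
#'   wearable camera does.
#' @param scene_px working scene resolution (width, height); the full
#'   native 1920 x 1080 is used for rendering regardless.
#' @param white_point_cdm2 luminance mapped to pixel value 255 (fixed
#'   exposure; recorded in the ground truth).
#' @return A `reading_sim_config` list.
#' @export
reading_config <- function(duration_s = 60,
                           page_size_cm = c(25.5, 26),
                           font_height_cm = 0.4,
                           viewing_distance_m = 0.5,
                           background_cdm2 = 90,
                           text_cdm2 = 2,
                           surround_cdm2 = 12,
                           fixation_mean_s = 0.22,
                           fixation_sd_s = 0.15,
                           saccade_deg = 2,
                           blink_rate_per_min = 10,
                           blink_mean_frames = 5,
                           pupil_mm = 3.70,
                           gaze_noise_deg = 0.15,
                           ink_coverage = 0.13,
                           camera_psf_px = 2,
                           scene_px = c(480, 270),
                           white_point_cdm2 = 100) {
  cfg <- as.list(environment())
  class(cfg) <- "reading_sim_config"
  cfg
}

#' Walking-session simulator configuration
#'
#' The stated world of the indoor walking task: corridors whose lights,
#' walls, floors and ceilings span the luminance bands 1,600-5,000,
#' 90-145, 70-90 and 40-65 cd/m^2; footsteps oscillating head pitch at
#' ~2 Hz; scheduled body turns producing sustained horizontal scene flow
#' and a symmetric 2-4 Hz optokinetic eye oscillation; an Alpha-shaped
#' fixation-distance distribution with mode near 1 m; and a blink rate
#' about three times the reading rate. The eye counter-rotates head
#' motion with a configurable lag, producing measurable head-eye
#' coordination reflexes. Head oscillation amplitudes are kept small
#' enough that compensatory eye-in-head velocity stays in the fixation
#' regime, so ground-truth labels remain well defined.
#'
#' @param duration_s session length.
#' @param light_cdm2,wall_cdm2,floor_cdm2,ceiling_cdm2 luminance bands.
#' @param step_hz head-pitch (footstep) oscillation frequency.
#' @param pitch_amp_deg head-pitch oscillation amplitude.
#' @param sway_hz,sway_amp_deg lateral yaw sway of normal gait.
#' @param turn_times_s,turn_dirs,turn_angle_deg,turn_duration_s the turn
#'   schedule (dirs +1 right / -1 left).
#' @param okn_freq_hz,okn_amp_deg turn-induced optokinetic oscillation
#'   (triangular, symmetric).
#' @param head_eye_lag_s eye counter-rotation lag (40-100 ms typical).
#' @param fixation_mean_s,fixation_sd_s fixation duration distribution.
#' @param blink_rate_per_min,blink_mean_frames blink statistics.
#' @param pupil_mm mean pupil diameter.
#' @param gaze_noise_deg per-sample gaze noise RMS.
#' @param scene_px working scene resolution (width, height).
#' @param white_point_cdm2 fixed-exposure white point.
#' @return A `walking_sim_config` list.
#' @export
walking_config <- function(duration_s = 60,
                           light_cdm2 = c(1600, 5000),
                           wall_cdm2 = c(90, 145),
                           floor_cdm2 = c(70, 90),
                           ceiling_cdm2 = c(40, 65),
                           step_hz = 2,
                           pitch_amp_deg = 0.3,
                           sway_hz = 0.9,
                           sway_amp_deg = 0.3,
                           turn_times_s = c(10, 22, 34, 46),
                           turn_dirs = c(1, -1, 1, -1),
                           turn_angle_deg = 90,
                           turn_duration_s = 2.5,
                           okn_freq_hz = 3,
                           okn_amp_deg = 1.5,
                           head_eye_lag_s = 0.08,
                           fixation_mean_s = 0.19,
                           fixation_sd_s = 0.13,
                           blink_rate_per_min = 30,
                           blink_mean_frames = 5,
                           pupil_mm = 4.7,
                           gaze_noise_deg = 0.15,
                           scene_px = c(480, 270),
                           white_point_cdm2 = 250) {
  cfg <- as.list(environment())
  class(cfg) <- "walking_sim_config"
  cfg
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# ---- shared low-level helpers -------------------------------------------

# average f x f blocks (h, w divisible by f)
box_downsample <- function(m, f) {
  h <- nrow(m); w <- ncol(m)
  m2 <- matrix(colMeans(matrix(m, nrow = f)), h / f, w)
  t(matrix(colMeans(matrix(t(m2), nrow = f)), w / f, h / f))
}

# separable Gaussian blur via shift-and-add, replicated borders; emulates
# the scene camera's optical point spread
gauss_blur <- function(m, sigma_px) {
  r <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-0.5 * ((-r):r)^2 / sigma_px^2)
  k <- k / sum(k)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (s in (-r):r) {
    rows <- pmin(pmax(seq_len(h) + s, 1L), h)
    out <- out + k[s + r + 1] * m[rows, ]
  }
  m2 <- matrix(0, h, w)
  for (s in (-r):r) {
    cols <- pmin(pmax(seq_len(w) + s, 1L), w)
    m2 <- m2 + k[s + r + 1] * out[, cols]
  }
  m2
}

# periodic 1/f spatial noise, standardized to sd 1
noise_1f <- function(h, w, exponent = 1) {
  z <- matrix(stats::rnorm(h * w), h, w)
  fy <- c(0:(floor(h / 2)), -(ceiling(h / 2) - 1):-1) / h
  fx <- c(0:(floor(w / 2)), -(ceiling(w / 2) - 1):-1) / w
  fr <- sqrt(outer(fy^2, fx^2, "+"))
  amp <- 1 / (fr + 1 / max(h, w))^exponent
  out <- Re(stats::fft(stats::fft(z) * amp, inverse = TRUE))
  (out - mean(out)) / stats::sd(out)
}

lum_to_px <- function(lum, white_point) {
  as.integer(round(pmin(pmax(lum / white_point, 0), 1) * 255))
}

# exponential blink process -> logical mask at rate_hz
gen_blink_mask <- function(duration_s, rate_per_min, mean_frames, rate_hz) {
  n <- round(duration_s * rate_hz)
  mask <- rep(FALSE, n)
  t <- stats::rexp(1, rate_per_min / 60)
  while (t < duration_s) {
    len <- max(1L, stats::rpois(1, mean_frames - 1) + 1L)
    i0 <- floor(t * rate_hz) + 1L
    mask[i0:min(i0 + len - 1L, n)] <- TRUE
    t <- t + len / rate_hz + stats::rexp(1, rate_per_min / 60)
  }
  mask
}

# triangular wave, amplitude A, frequency f, zero-mean, symmetric
triangle_wave <- function(t, f, A) {
  ph <- (t * f) %% 1
  A * (4 * abs(ph - 0.5) - 1)
}

# ---- synthetic eye images ------------------------------------------------

#' Render labelled synthetic eye images
#'
#' Deterministic generator of eyes-open and eyes-closed image classes for
#' training/validating the blink classifier. Open images contain a dark
#' pupil disc inside an iris annulus with a specular highlight on a bright
#' sclera; closed images contain horizontal lid-texture gradients with a
#' darker lash line. Appearance parameters are jittered per image.
#'
#' @param n_open,n_closed image counts per class (>= 1). The reference
#'   class imbalance of real recordings (161 closed / 839 open) can be
#'   reproduced directly.
#' @param px image side length.
#' @param seed RNG seed.
#' @return List with `images` (array `px x px x (n_open+n_closed)`, 0..255)
#'   and `labels` (character, `"open"`/`"closed"`).
#' @export
render_synthetic_eye_images <- function(n_open, n_closed, px = 36, seed = 1) {
  stopifnot(n_open >= 1, n_closed >= 1)
  with_seed(seed, {
    n <- n_open + n_closed
    imgs <- array(0, c(px, px, n))
    gi <- matrix(rep(seq_len(px), px), px); gj <- t(gi)
    for (k in seq_len(n_open)) {
      cx <- px / 2 + stats::runif(1, -3, 3)
      cy <- px / 2 + stats::runif(1, -2, 2)
      r_iris <- px * stats::runif(1, 0.28, 0.36)
      r_pupil <- r_iris * stats::runif(1, 0.35, 0.5)
      d <- sqrt((gi - cy)^2 + (gj - cx)^2)
      img <- matrix(200, px, px)
      img[d < r_iris] <- 95 + 25 * sin(d[d < r_iris])
      img[d < r_pupil] <- 25
      sx <- cx + stats::runif(1, -2, 2); sy <- cy - r_pupil / 2
      img[sqrt((gi - sy)^2 + (gj - sx)^2) < 1.5] <- 250
      img <- img + matrix(stats::rnorm(px * px, 0, 8), px)
      imgs[, , k] <- pmin(pmax(img, 0), 255)
    }
    for (k in seq_len(n_closed)) {
      base <- 180 - 60 * (gi / px) +
        15 * sin(2 * pi * gi / stats::runif(1, 6, 12))
      lash <- round(px * stats::runif(1, 0.45, 0.6))
      base[pmax(1, lash - 1):min(px, lash + 1), ] <-
        base[pmax(1, lash - 1):min(px, lash + 1), ] - 70
      base <- base + matrix(stats::rnorm(px * px, 0, 8), px)
      imgs[, , n_open + k] <- pmin(pmax(base, 0), 255)
    }
    list(images = imgs,
         labels = c(rep("open", n_open), rep("closed", n_closed)))
  })
}

# pool-based eye-frame stack for a session
render_eye_frames <- function(blink_mask, px = 48, seed = 1) {
  pool <- render_synthetic_eye_images(40, 15, px = px, seed = seed)
  open_idx <- which(pool$labels == "open")
  closed_idx <- which(pool$labels == "closed")
  n <- length(blink_mask)
  pick <- ifelse(blink_mask,
                 closed_idx[(seq_len(n) %% length(closed_idx)) + 1L],
                 open_idx[(seq_len(n) %% length(open_idx)) + 1L])
  out <- array(as.raw(0), c(px, px, n))
  for (i in seq_len(n))
    out[, , i] <- as.raw(as.integer(round(pool$images[, , pick[i]])))
  out
}

# ---- reading -------------------------------------------------------------

#' Simulate a reading session
#'
#' Generates a complete session (scene frames, eye frames, gaze, IMU) plus
#' ground truth for the reading task described in [reading_config()].
#' The retinal consequences arise by construction: fixating mid-page puts
#' ink and page white in the fovea (dark-skewed luminance) and the bright
#' page edge against the dim surround in the periphery (light-skewed).
#'
#' @param config a [reading_config()].
#' @param seed RNG seed (full determinism).
#' @return List with `session` (a `session_bundle`) and `truth` (a
#'   `ground_truth` list: per-sample `labels` data.frame, `blink_mask`,
#'   `events`, luminance mapping, config echo).
#' @export
simulate_reading_session <- function(config = reading_config(), seed = 1) {
  stopifnot(inherits(config, "reading_sim_config"))
  with_seed(seed, sim_reading_impl(config))
}

sim_reading_impl <- function(cfg) {
  D_m <- cfg$viewing_distance_m
  page_half_deg <- atan(cfg$page_size_cm / 2 / (100 * D_m)) * 180 / pi
  if (2 * min(page_half_deg) <= 5)
    stop("page smaller than the fovea at the given viewing distance")
  font_deg <- atan(cfg$font_height_cm / (100 * D_m)) * 180 / pi

  # --- scene: render once at native resolution, downsample to working px
  native <- c(1920L, 1080L)
  fov <- c(82, 52)
  ppd_n <- native / fov
  img <- matrix(cfg$surround_cdm2, native[2], native[1])
  pc <- native / 2
  px_x <- round(pc[1] + c(-1, 1) * page_half_deg[1] * ppd_n[1])
  px_y <- round(pc[2] + c(-1, 1) * page_half_deg[2] * ppd_n[2])
  img[px_y[1]:px_y[2], px_x[1]:px_x[2]] <- cfg$background_cdm2
  font_px <- font_deg * ppd_n[2]
  line_pitch_px <- round(2 * font_px)
  line_rows <- seq(px_y[1] + 2 * line_pitch_px, px_y[2] - line_pitch_px,
                   by = line_pitch_px)
  page_w <- px_x[2] - px_x[1] + 1L
  stroke_w <- 2L
  gap_mean <- round(stroke_w * (1 - cfg$ink_coverage * 2) /
                      (cfg$ink_coverage * 2))
  for (r in line_rows) {
    x <- px_x[1] + round(stats::runif(1, 4, 30))
    line_end <- px_x[2] - round(stats::runif(1, 4, 30))
    word_left <- round(stats::runif(1, 25, 70))
    while (x < line_end) {
      img[r:(r + round(font_px) - 1L), x:min(x + stroke_w - 1L, line_end)] <-
        cfg$text_cdm2
      word_left <- word_left - stroke_w - gap_mean
      if (word_left <= 0) {   # word space
        x <- x + stroke_w + round(stats::runif(1, 10, 18))
        word_left <- round(stats::runif(1, 25, 70))
      } else {
        x <- x + stroke_w + max(1L, stats::rpois(1, gap_mean))
      }
    }
  }
  f_down <- native[1] / cfg$scene_px[1]
  stopifnot(f_down == round(f_down), native[2] / cfg$scene_px[2] == f_down)
  img <- gauss_blur(img, cfg$camera_psf_px)   # camera optics
  frame_px <- lum_to_px(box_downsample(img, f_down), cfg$white_point_cdm2)
  dim(frame_px) <- c(cfg$scene_px[2], cfg$scene_px[1])

  n_scene <- round(cfg$duration_s * 25)
  scene <- array(as.raw(frame_px), c(cfg$scene_px[2], cfg$scene_px[1], n_scene))

  # --- gaze: line scanning over the text rows
  line_el <- (line_rows + font_px / 2 - pc[2]) / ppd_n[2]
  az_lo <- -page_half_deg[1] + 1.5
  az_hi <- page_half_deg[1] - 1.5
  events <- list()
  cur <- 0; li <- 1; az <- az_lo
  while (cur < cfg$duration_s) {
    fd <- max(0.08, stats::rnorm(1, cfg$fixation_mean_s, cfg$fixation_sd_s))
    events[[length(events) + 1L]] <-
      list(type = "fixation", t0 = cur, t1 = cur + fd,
           az0 = az, el0 = line_el[li], az1 = az, el1 = line_el[li])
    cur <- cur + fd
    if (az + cfg$saccade_deg <= az_hi) {
      az2 <- az + cfg$saccade_deg; li2 <- li; sd_s <- 0.04
    } else {
      az2 <- az_lo; li2 <- if (li < length(line_el)) li + 1L else 1L
      sd_s <- 0.08
    }
    events[[length(events) + 1L]] <-
      list(type = "saccade", t0 = cur, t1 = cur + sd_s,
           az0 = az, el0 = line_el[li], az1 = az2, el1 = line_el[li2])
    cur <- cur + sd_s
    az <- az2; li <- li2
  }
  ras <- rasterize_gaze_events(events, cfg$duration_s, 50)

  blink <- gen_blink_mask(cfg$duration_s, cfg$blink_rate_per_min,
                          cfg$blink_mean_frames, 50)
  gaze <- make_gaze_stream(ras, blink, cfg$gaze_noise_deg,
                           dist_mm = rep(D_m * 1000, length(ras$t)),
                           pupil_mm = cfg$pupil_mm, fov = fov)

  # --- imu: near-stationary head with slow drift
  t_imu <- (seq_len(round(cfg$duration_s * 100)) - 1) / 100
  gy <- cbind(0.2 * 2 * pi * 0.3 * cos(2 * pi * 0.3 * t_imu) +
                stats::rnorm(length(t_imu), 0, 1),
              stats::rnorm(length(t_imu), 0, 1),
              stats::rnorm(length(t_imu), 0, 0.5))
  ac <- cbind(stats::rnorm(length(t_imu), 0, 0.1),
              -9.81 + stats::rnorm(length(t_imu), 0, 0.1),
              stats::rnorm(length(t_imu), 0, 0.1))
  imu <- imu_stream(t_imu, ac, gy)

  eye_frames <- render_eye_frames(blink, px = 48,
                                  seed = stats::runif(1, 1, 1e6))
  cam <- camera_model(scene_fov_deg = fov,
                      scene_resolution_px = cfg$scene_px,
                      eye_resolution_px = c(48, 48))
  session <- session_bundle(cam, scene, eye_frames, gaze, imu,
                            task_label = "reading",
                            duration_s = cfg$duration_s)
  truth <- list(labels = data.frame(t = ras$t, label = ras$label,
                                    blink = blink),
                blink_mask = blink,
                turn_times_s = numeric(0),
                events = events,
                lum_mapping = c(white_point_cdm2 = cfg$white_point_cdm2),
                config = cfg)
  class(truth) <- "ground_truth"
  list(session = session, truth = truth)
}

# piecewise fixation/saccade events -> 50 Hz az/el/label
rasterize_gaze_events <- function(events, duration_s, rate_hz) {
  t <- (seq_len(round(duration_s * rate_hz)) - 1) / rate_hz
  az <- numeric(length(t)); el <- numeric(length(t))
  lab <- character(length(t))
  for (ev in events) {
    sel <- which(t >= ev$t0 & t < ev$t1)
    if (!length(sel)) next
    # midpoint sampling phase: a sample integrates over its frame period
    frac <- pmin((t[sel] - ev$t0 + 0.5 / rate_hz) /
                   max(ev$t1 - ev$t0, 1e-9), 1)
    az[sel] <- ev$az0 + frac * (ev$az1 - ev$az0)
    el[sel] <- ev$el0 + frac * (ev$el1 - ev$el0)
    # observable-state labels: a sample that already records the landed
    # position is a fixation sample to any observer
    lab[sel] <- ifelse(ev$type == "saccade" & frac >= 1, "fixation", ev$type)
  }
  # fill any trailing unlabelled samples with the last event state
  if (any(lab == "")) {
    last <- events[[length(events)]]
    sel <- which(lab == "")
    az[sel] <- last$az1; el[sel] <- last$el1; lab[sel] <- last$type
  }
  list(t = t, az = az, el = el, label = lab)
}

make_gaze_stream <- function(ras, blink, noise_deg, dist_mm, pupil_mm, fov) {
  n <- length(ras$t)
  az <- ras$az + stats::rnorm(n, 0, noise_deg)
  el <- ras$el + stats::rnorm(n, 0, noise_deg)
  gp <- cbind(0.5 + az / fov[1], 0.5 + el / fov[2])
  gp3 <- cbind(tan(az * pi / 180) * dist_mm,
               tan(el * pi / 180) * dist_mm,
               dist_mm)
  pd <- pupil_mm + 0.05 * stats::rnorm(1) +
    0.1 * sin(2 * pi * 0.05 * ras$t) + stats::rnorm(n, 0, 0.03)
  validity <- !blink
  gaze_stream(ras$t, gp, gp3, pd_left = pd,
              pd_right = pd + stats::rnorm(n, 0, 0.02), validity = validity)
}

# ---- walking -------------------------------------------------------------

#' Simulate a walking session
#'
#' Generates an indoor-corridor walking session per [walking_config()]:
#' a 1/f-textured corridor panorama with the configured luminance bands
#' and ceiling lights, ego-motion panning with gait sway and footstep
#' pitch bob, scheduled turns injecting sustained horizontal flow plus a
#' symmetric triangular optokinetic eye oscillation, lagged eye
#' counter-rotation of head motion, and a higher blink rate than reading.
#'
#' @param config a [walking_config()].
#' @param seed RNG seed.
#' @return List with `session` and `truth` as in
#'   [simulate_reading_session()]; `truth$turn_times_s` holds the centre
#'   time of each scheduled turn.
#' @export
simulate_walking_session <- function(config = walking_config(), seed = 1) {
  stopifnot(inherits(config, "walking_sim_config"))
  if (any(config$turn_times_s < 0 |
            config$turn_times_s + config$turn_duration_s > config$duration_s))
    stop("turn schedule outside session")
  if (length(config$turn_dirs) != length(config$turn_times_s))
    stop("turn_dirs must match turn_times_s")
  with_seed(seed, sim_walking_impl(config))
}

sim_walking_impl <- function(cfg) {
  w_px <- cfg$scene_px[1]; h_px <- cfg$scene_px[2]
  fov <- c(82, 52)
  ppd <- c(w_px, h_px) / fov

  # --- corridor panorama (wrapping horizontally)
  margin <- 16L
  H <- h_px + 2L * margin
  W <- 2048L
  tex <- noise_1f(H, W, exponent = 1.2)
  tex <- 1 + 0.25 * pmin(pmax(tex, -2), 2) / 2
  elev <- ((seq_len(H) - margin) - h_px / 2) / ppd[2]   # deg, + is down
  base <- numeric(H)
  runif1 <- function(r) stats::runif(1, r[1], r[2])
  base[elev < -15] <- runif1(cfg$ceiling_cdm2)
  base[elev >= -15 & elev < 12] <- runif1(cfg$wall_cdm2)
  base[elev >= 12] <- runif1(cfg$floor_cdm2)
  pano <- tex * matrix(base, H, W)
  # posters and doors on the walls: corridor walls carry high-contrast
  # rectangular content that attracts fixations
  posters <- list()
  px_x <- 60
  while (px_x < W - 80) {
    pw <- round(stats::runif(1, 40, 80))
    ph <- round(stats::runif(1, 50, 90))
    pr <- margin + round((stats::runif(1, -9, 5) + fov[2] / 2) * ppd[2])
    rows <- max(1, pr - ph %/% 2):min(H, pr + ph %/% 2)
    cols <- px_x:min(W, px_x + pw)
    lum <- if (stats::runif(1) < 0.6) stats::runif(1, 150, 400)
           else stats::runif(1, 8, 40)   # bright poster or dark door
    patch_tex <- 1 + 0.3 * (tex[rows, cols] - 1) / 0.25 * 0.25 +
      0.15 * matrix(stats::rnorm(length(rows) * length(cols)),
                    length(rows))
    pano[rows, cols] <- lum * pmax(patch_tex, 0.2)
    # dark frame
    pano[rows[c(1, length(rows))], cols] <- 10
    pano[rows, cols[c(1, length(cols))]] <- 10
    posters[[length(posters) + 1L]] <-
      c(az_deg = (px_x + pw / 2) / ppd[1],
        el_deg = (pr - margin - h_px / 2) / ppd[2])
    px_x <- px_x + pw + round(stats::runif(1, 60, 160))
  }
  poster_pos <- do.call(rbind, posters)
  # ceiling lights: bright discs along the ceiling band
  light_row <- margin + round((-20 - (-fov[2] / 2)) * ppd[2])
  gi <- matrix(rep(seq_len(H), W), H); gj <- matrix(rep(seq_len(W), each = H), H)
  for (cx in seq(40, W - 40, by = round(stats::runif(1, 150, 190)))) {
    lum <- runif1(cfg$light_cdm2)
    d2 <- (gi - light_row)^2 + pmin(abs(gj - cx), W - abs(gj - cx))^2
    pano[d2 < 81] <- lum
  }
  pano_px <- matrix(pmin(pmax(pano / cfg$white_point_cdm2, 0), 1) * 255, H, W)

  # --- head orientation (analytic position and velocity)
  turn_T <- cfg$turn_duration_s
  yaw_fun <- function(t) {
    y <- cfg$sway_amp_deg * sin(2 * pi * cfg$sway_hz * t)
    for (k in seq_along(cfg$turn_times_s)) {
      x <- pmin(pmax((t - cfg$turn_times_s[k]) / turn_T, 0), 1)
      y <- y + cfg$turn_dirs[k] * cfg$turn_angle_deg *
        (x - sin(2 * pi * x) / (2 * pi))
    }
    y
  }
  yaw_vel_fun <- function(t) {
    v <- cfg$sway_amp_deg * 2 * pi * cfg$sway_hz * cos(2 * pi * cfg$sway_hz * t)
    for (k in seq_along(cfg$turn_times_s)) {
      x <- (t - cfg$turn_times_s[k]) / turn_T
      inside <- x >= 0 & x <= 1
      v <- v + ifelse(inside, cfg$turn_dirs[k] * cfg$turn_angle_deg / turn_T *
                        (1 - cos(2 * pi * pmin(pmax(x, 0), 1))), 0)
    }
    v
  }
  pitch_fun <- function(t) cfg$pitch_amp_deg * sin(2 * pi * cfg$step_hz * t)
  pitch_vel_fun <- function(t)
    cfg$pitch_amp_deg * 2 * pi * cfg$step_hz * cos(2 * pi * cfg$step_hz * t)

  # --- scene frames: bilinear crops of the panorama
  n_scene <- round(cfg$duration_s * 25)
  t_scene <- (seq_len(n_scene) - 1) / 25
  scene <- array(as.raw(0), c(h_px, w_px, n_scene))
  rows0 <- margin + seq_len(h_px)
  for (f in seq_len(n_scene)) {
    cx <- yaw_fun(t_scene[f]) * ppd[1]
    cy <- pitch_fun(t_scene[f]) * ppd[2]
    j <- cx %% W; j0 <- floor(j); aj <- j - j0
    i0 <- floor(cy); ai <- cy - i0
    cols1 <- ((j0 + seq_len(w_px) - 1L) %% W) + 1L
    cols2 <- (cols1 %% W) + 1L
    r1 <- pmin(pmax(rows0 + i0, 1L), H); r2 <- pmin(r1 + 1L, H)
    fm <- (1 - ai) * ((1 - aj) * pano_px[r1, cols1] + aj * pano_px[r1, cols2]) +
      ai * ((1 - aj) * pano_px[r2, cols1] + aj * pano_px[r2, cols2])
    scene[, , f] <- as.raw(as.integer(round(fm)))
  }

  # --- gaze: fixations on world points, OKN during turns, lagged VOR
  rate <- 50
  t50 <- (seq_len(round(cfg$duration_s * rate)) - 1) / rate
  n <- length(t50)
  lag <- cfg$head_eye_lag_s
  in_turn <- rep(FALSE, n)
  for (k in seq_along(cfg$turn_times_s))
    in_turn <- in_turn | (t50 >= cfg$turn_times_s[k] &
                            t50 <= cfg$turn_times_s[k] + turn_T)
  az <- numeric(n); el <- numeric(n); lab <- character(n); dist <- numeric(n)
  state <- "fixation"
  tgt_az <- yaw_fun(0) + stats::runif(1, -8, 8)
  tgt_el <- stats::runif(1, -4, 6)
  fix_end <- max(0.08, stats::rnorm(1, cfg$fixation_mean_s, cfg$fixation_sd_s))
  fix_dist <- (0.5 + stats::rgamma(1, shape = 2, scale = 0.4)) * 1000
  sac_from <- c(0, 0); sac_t0 <- 0; sac_t1 <- 0; sac_to <- c(0, 0)
  for (i in seq_len(n)) {
    tt <- t50[i]
    yaw_l <- yaw_fun(tt - lag); pitch_l <- pitch_fun(tt - lag)
    if (in_turn[i]) {
      az[i] <- triangle_wave(tt, cfg$okn_freq_hz, cfg$okn_amp_deg)
      el[i] <- tgt_el - pitch_l
      lab[i] <- "smooth_pursuit"
      dist[i] <- 3000
      state <- "fixation"   # re-fixate after the turn
      fix_end <- tt + 0.02
      next
    }
    if (state == "fixation" && tt >= fix_end) {
      # plan a saccade to a fresh target at least 2 degrees away
      # (sub-degree relocations are below tracker noise, not saccades)
      sac_from <- c(az[max(i - 1, 1)], el[max(i - 1, 1)])
      repeat {
        # posters attract about half of the fixations; the rest scatter
        # over the scene ahead
        yaw_now <- yaw_fun(tt)
        span <- W / ppd[1]   # panorama wrap period in degrees
        daz <- ((poster_pos[, 1] - yaw_now + span / 2) %% span) - span / 2
        near <- which(abs(daz) < 9)
        if (length(near) && stats::runif(1) < 0.5) {
          pick <- near[sample.int(length(near), 1)]
          tgt_az <- yaw_now + daz[pick] + stats::runif(1, -1, 1)
          tgt_el <- poster_pos[pick, 2] + stats::runif(1, -1.5, 1.5)
        } else {
          tgt_az <- yaw_now + stats::runif(1, -8, 8)
          tgt_el <- stats::runif(1, -4, 6)
        }
        if (sqrt((tgt_az - yaw_fun(tt - lag) - sac_from[1])^2 +
                   (tgt_el - pitch_fun(tt - lag) - sac_from[2])^2) >= 2)
          break
      }
      fix_dist <- (0.5 + stats::rgamma(1, shape = 2, scale = 0.4)) * 1000
      sac_t0 <- tt; sac_t1 <- tt + 0.04
      sac_to <- c(tgt_az - yaw_l, tgt_el - pitch_l)
      state <- "saccade"
    }
    if (state == "saccade") {
      # midpoint sampling phase, as in the reading rasterizer; a sample
      # recording the landed position already counts as fixation
      frac <- (tt - sac_t0 + 0.5 / rate) / (sac_t1 - sac_t0)
      if (frac < 1) {
        # target continuously re-expressed in eye-in-head coordinates, so
        # the saccade lands exactly where fixation tracking resumes
        sac_to <- c(tgt_az - yaw_l, tgt_el - pitch_l)
        az[i] <- sac_from[1] + frac * (sac_to[1] - sac_from[1])
        el[i] <- sac_from[2] + frac * (sac_to[2] - sac_from[2])
        lab[i] <- "saccade"
        dist[i] <- fix_dist
        next
      }
      state <- "fixation"
      fix_end <- tt + max(0.08, stats::rnorm(1, cfg$fixation_mean_s,
                                             cfg$fixation_sd_s))
    }
    az[i] <- tgt_az - yaw_l
    el[i] <- tgt_el - pitch_l
    lab[i] <- "fixation"
    dist[i] <- fix_dist
  }
  ras <- list(t = t50, az = az, el = el, label = lab)
  blink <- gen_blink_mask(cfg$duration_s, cfg$blink_rate_per_min,
                          cfg$blink_mean_frames, rate)
  gaze <- make_gaze_stream(ras, blink, cfg$gaze_noise_deg, dist_mm = dist,
                           pupil_mm = cfg$pupil_mm, fov = fov)

  # --- imu
  t_imu <- (seq_len(round(cfg$duration_s * 100)) - 1) / 100
  gy <- cbind(pitch_vel_fun(t_imu) + stats::rnorm(length(t_imu), 0, 1),
              yaw_vel_fun(t_imu) + stats::rnorm(length(t_imu), 0, 1),
              stats::rnorm(length(t_imu), 0, 1))
  step_ac <- 1.5 * sin(2 * pi * cfg$step_hz * t_imu + pi / 3)
  ac <- cbind(step_ac + stats::rnorm(length(t_imu), 0, 0.3),
              -9.81 + step_ac * 0.5 + stats::rnorm(length(t_imu), 0, 0.3),
              stats::rnorm(length(t_imu), 0, 0.3))
  imu <- imu_stream(t_imu, ac, gy)

  eye_frames <- render_eye_frames(blink, px = 48,
                                  seed = stats::runif(1, 1, 1e6))
  cam <- camera_model(scene_fov_deg = fov, scene_resolution_px = cfg$scene_px,
                      eye_resolution_px = c(48, 48))
  session <- session_bundle(cam, scene, eye_frames, gaze, imu,
                            task_label = "walking",
                            duration_s = cfg$duration_s)
  truth <- list(labels = data.frame(t = t50, label = lab, blink = blink),
                blink_mask = blink,
                turn_times_s = cfg$turn_times_s + turn_T / 2,
                events = NULL,
                lum_mapping = c(white_point_cdm2 = cfg$white_point_cdm2),
                config = cfg)
  class(truth) <- "ground_truth"
  list(session = session, truth = truth)
}

#' Save ground truth next to a session directory
#'
#' Writes `truth.csv` (per-sample labels) and `truth.json` (turn schedule,
#' luminance mapping, config echo) into a session directory.
#'
#' @param truth a `ground_truth`.
#' @param path session directory.
#' @return `path`, invisibly.
#' @export
save_ground_truth <- function(truth, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(truth$labels, file.path(path, "truth.csv"),
                   row.names = FALSE)
  meta <- list(turn_times_s = truth$turn_times_s,
               lum_mapping = as.list(truth$lum_mapping),
               config = truth$config[!vapply(truth$config, is.function,
                                             logical(1))])
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             file.path(path, "truth.json"))
  invisible(path)
}
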