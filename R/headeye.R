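#' Detect high-velocity head events for one direction
#'
#' Marks times when the gyroscope velocity along one axis exceeds a
#' direction-specific threshold of `k` times the median velocity of that
#' direction (the median of the signed half of the trace: positive samples
#' for right/up, sign-flipped negative samples for left/down). Events
#' closer than the refractory period to the previous event are suppressed
#' ("one time stamp every 50 ms").
#'
#' @param t gyro sample times (s).
#' @param gy_axis signed angular velocity for the relevant axis (deg/s);
#'   pitch for up/down, yaw for right/left.
#' @param direction `"right"`, `"left"`, `"up"` or `"down"`; right/up take
#'   the positive half of the signal.
#' @param k threshold multiplier over the median (2.5 by convention).
#' @param refractory_s minimum inter-event time.
#' @return A `head_event_set` list: `direction`, `threshold_dps`, `times`,
#'   `velocities`.
#' @export
head_velocity_events <- function(t, gy_axis, direction = c("right", "left",
                                                           "up", "down"),
                                 k = 2.5, refractory_s = 0.05) {
  direction <- match.arg(direction)
  if (length(t) < 2 || diff(range(t)) < 1) stop("need at least 1 s of data")
  sgn <- if (direction %in% c("right", "up")) 1 else -1
  v <- sgn * gy_axis
  pos <- v[v > 0 & is.finite(v)]
  if (!length(pos)) {
    warning("no samples in direction ", direction)
    out <- list(direction = direction, threshold_dps = NA_real_,
                times = numeric(0), velocities = numeric(0))
    class(out) <- "head_event_set"
    return(out)
  }
  thr <- k * stats::median(pos)
  cand <- which(is.finite(v) & v > thr)
  keep <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (t[i] - last >= refractory_s - 1e-9) {
      keep <- c(keep, i)
      last <- t[i]
    }
  }
  out <- list(direction = direction, threshold_dps = thr,
              times = t[keep], velocities = v[keep])
  class(out) <- "head_event_set"
  out
}

#' Event-triggered average eye movement
#'
#' Averages snippets of the eye-position trace centred at each head-event
#' time: per-event windows of `+/- window_s` are aligned at lag 0 and
#' averaged sample-wise. Events whose window extends beyond the recording
#' are dropped; snippets overlapping a blink mask for more than 40% of
#' their samples are excluded. Optionally the average is min-max
#' normalized to `[0, 1]` (the conventional display form).
#'
#' @param t eye sample times (s), regular rate.
#' @param eye eye position trace (deg), same length as `t`.
#' @param event_times head event times (s).
#' @param window_s half window (s); typical values: 1 for sedentary tasks,
#'   0.5 for locomotion (the reflex is about twice as fast).
#' @param blink_mask optional logical vector (TRUE = blink) parallel to `t`.
#' @param normalize min-max normalize the average trace.
#' @return A `triggered_average` list: `lag_s` (centred at 0), `mean`,
#'   `n_events`, `traces` (snippet matrix), `normalized`.
#' @export
triggered_eye_average <- function(t, eye, event_times, window_s = 1,
                                  blink_mask = NULL, normalize = FALSE) {
  dt <- stats::median(diff(t))
  half <- round(window_s / dt)
  lag_s <- (-half:half) * dt
  snips <- list()
  for (te in event_times) {
    ci <- which.min(abs(t - te))
    i0 <- ci - half; i1 <- ci + half
    if (i0 < 1 || i1 > length(t)) next
    if (!is.null(blink_mask) &&
        mean(blink_mask[i0:i1], na.rm = TRUE) > 0.4) next
    snips[[length(snips) + 1L]] <- eye[i0:i1]
  }
  if (!length(snips)) stop("no usable events (windows outside recording?)")
  m <- do.call(rbind, snips)
  avg <- colMeans(m, na.rm = TRUE)
  if (normalize) {
    rng <- range(avg, na.rm = TRUE)
    if (diff(rng) > 0) avg <- (avg - rng[1]) / diff(rng)
  }
  out <- list(lag_s = lag_s, mean = avg, n_events = nrow(m), traces = m,
              normalized = isTRUE(normalize))
  class(out) <- "triggered_average"
  out
}

#' Dominant head-pitch oscillation frequency
#'
#' Peak of the power spectrum of the linearly detrended pitch-velocity
#' trace, restricted to 0.2-10 Hz. Footsteps during locomotion show up as
#' a ~2 Hz peak; sedentary tasks sit at or below ~0.5 Hz.
#'
#' @param t gyro sample times (s), regular rate.
#' @param gy_pitch pitch angular velocity (deg/s).
#' @param band frequency search band (Hz).
#' @return Peak frequency in Hz.
#' @export
dominant_pitch_frequency <- function(t, gy_pitch, band = c(0.2, 10)) {
  ok <- is.finite(gy_pitch)
  t <- t[ok]; x <- gy_pitch[ok]
  if (diff(range(t)) < 5) stop("need at least 5 s of data")
  x <- stats::resid(stats::lm(x ~ t))      # linear detrend
  dt <- stats::median(diff(t))
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  freq <- (seq_len(n) - 1) / (n * dt)
  sel <- freq >= band[1] & freq <= band[2]
  freq[sel][which.max(p[sel])]
}
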