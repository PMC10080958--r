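#' Quadratic polynomial expansion of an image
#'
#' Per-pixel weighted least-squares fit of the local quadratic model
#' `f(x) = x^T A x + b^T x + c` over 5 x 5 windows with Gaussian
#' applicability weights (sigma = 1.1 by default); the building block of
#' the displacement estimator. Coordinates: `x` = column offset, `y` = row
#' offset.
#'
#' @param img numeric matrix (grayscale image, any scale).
#' @param sigma Gaussian applicability sd (px).
#' @return List of per-pixel coefficient matrices `c`, `bx`, `by`, `axx`,
#'   `ayy`, `axy` (with `A = [[axx, axy], [axy, ayy]]`).
#' @export
polynomial_expansion <- function(img, sigma = 1.1) {
  .poly_exp_cpp(as.matrix(img), sigma)
}

#' Dense displacement field between two frames
#'
#' Coarse-to-fine estimation over an image pyramid (5 scales, halving
#' resolution with binomial anti-aliasing) with 10 refinement iterations
#' per scale; at each iteration the displacement is solved from paired
#' polynomial-expansion coefficients and the normal equations are averaged
#' over a 25 x 25 pixel region to smooth the estimates. Positive `dx`
#' means scene content moving rightward in the image.
#'
#' @param frame_a,frame_b same-size grayscale matrices (values 0..255 or
#'   0..1).
#' @param scales pyramid levels.
#' @param iterations refinement iterations per level.
#' @param sigma applicability sd of the 5x5 expansion window.
#' @param smooth_px side of the averaging region at full resolution.
#' @return A `flow_field` list: `dx`, `dy` (px/frame), `scales`,
#'   `iterations`.
#' @export
polynomial_expansion_flow <- function(frame_a, frame_b, scales = 5,
                                      iterations = 10, sigma = 1.1,
                                      smooth_px = 25) {
  res <- .fb_flow_cpp(as.matrix(frame_a), as.matrix(frame_b),
                      levels = as.integer(scales),
                      iters = as.integer(iterations),
                      sigma = sigma, smooth_win = as.integer(smooth_px))
  out <- list(dx = res$dx, dy = res$dy, scales = res$levels,
              iterations = res$iters)
  class(out) <- "flow_field"
  out
}

#' Average horizontal scene flow of a session
#'
#' Mean horizontal displacement (px/frame) across all pixels for each
#' consecutive scene-frame pair, optionally converted to deg/s through the
#' sampling density and frame rate. Frames wider than `max_width_px` are
#' downscaled first (desk-scale default 480 px).
#'
#' @param frames raw/numeric array `(h, w, n)` or a `session_bundle`.
#' @param camera a [camera_model()] (taken from the session if given).
#' @param max_width_px downscale limit.
#' @param ... passed to [polynomial_expansion_flow()].
#' @return A `horizontal_flow_trace` data.frame: `t` (time of the earlier
#'   frame of each pair), `mean_dx_px`, `mean_dx_dps`.
#' @export
average_horizontal_flow <- function(frames, camera = NULL,
                                    max_width_px = 480, ...) {
  if (inherits(frames, "session_bundle")) {
    camera <- frames$camera
    frames <- frames$scene_frames
  }
  d <- dim(frames)
  if (d[3] < 2) stop("need at least 2 frames")
  scale <- 1
  get_frame <- function(i) {
    m <- frames[, , i]
    storage.mode(m) <- "integer"
    m <- m / 255
    if (d[2] > max_width_px) {
      m <- resize_gray(m, round(d[1] * max_width_px / d[2]), max_width_px)
    }
    m
  }
  if (d[2] > max_width_px) scale <- max_width_px / d[2]
  mean_dx <- numeric(d[3] - 1)
  prev <- get_frame(1)
  for (i in 2:d[3]) {
    cur <- get_frame(i)
    fl <- polynomial_expansion_flow(prev, cur, ...)
    mean_dx[i - 1] <- mean(fl$dx) / scale
    prev <- cur
  }
  rate <- if (!is.null(camera)) camera$scene_rate_hz else NA_real_
  ppd_h <- if (!is.null(camera)) d[2] / camera$scene_fov_deg[1] else NA_real_
  out <- data.frame(t = (seq_len(d[3] - 1) - 1) / ifelse(is.na(rate), 1, rate),
                    mean_dx_px = mean_dx,
                    mean_dx_dps = mean_dx / ppd_h * rate)
  class(out) <- c("horizontal_flow_trace", class(out))
  out
}

#' Detect peaks in the horizontal flow trace
#'
#' Local maxima of the absolute flow trace (5-frame moving-average
#' smoothed) exceeding `threshold_frac` of a reference maximum; peaks in
#' the final `exclude_tail_s` of the recording are excluded (end-of-task
#' artefacts), and peaks must be at least `min_sep_s` apart. Absolute flow
#' is used because turns occur in both directions. In single-session mode
#' the reference maximum is the trace's own maximum; pass an external
#' `reference_max` for cohort-calibrated thresholds.
#'
#' @param trace a `horizontal_flow_trace` (or data.frame with `t` and
#'   `mean_dx_px`).
#' @param reference_max reference maximum of |flow|; `NULL` = session max.
#' @param threshold_frac threshold as a fraction of the reference maximum.
#' @param exclude_tail_s seconds excluded at the end of the recording.
#' @param min_sep_s minimum peak separation.
#' @return Data.frame `peak_t`, `peak_flow_px` (signed value at the peak).
#' @export
detect_flow_peaks <- function(trace, reference_max = NULL,
                              threshold_frac = 0.2, exclude_tail_s = 10,
                              min_sep_s = 0.5) {
  if (!nrow(trace)) stop("empty flow trace")
  x <- abs(trace$mean_dx_px)
  x_s <- stats::filter(x, rep(1 / 5, 5), sides = 2)
  x_s[is.na(x_s)] <- x[is.na(x_s)]
  x_s <- as.numeric(x_s)
  if (is.null(reference_max)) reference_max <- max(x_s)
  thr <- threshold_frac * reference_max
  n <- length(x_s)
  is_peak <- c(FALSE, x_s[2:(n - 1)] > x_s[1:(n - 2)] &
                 x_s[2:(n - 1)] >= x_s[3:n], FALSE)
  cand <- which(is_peak & x_s > thr)
  t_end <- max(trace$t)
  cand <- cand[trace$t[cand] <= t_end - exclude_tail_s]
  # enforce separation, keeping the larger peak
  cand <- cand[order(-x_s[cand])]
  keep <- integer(0)
  for (i in cand) {
    if (!length(keep) || all(abs(trace$t[i] - trace$t[keep]) >= min_sep_s))
      keep <- c(keep, i)
  }
  keep <- sort(keep)
  data.frame(peak_t = trace$t[keep], peak_flow_px = trace$mean_dx_px[keep])
}

#' Extract optokinetic-nystagmus segments around flow peaks
#'
#' For each flow peak, takes the 100-sample (+/- 1 s at 50 Hz) horizontal
#' eye-position window centred at the peak. Segments with fewer than 60
#' valid (non-blink, finite) samples, or whose window extends beyond the
#' recording, are rejected; remaining invalid samples are linearly
#' interpolated for the spectral analysis.
#'
#' @param t eye sample times (s) at the eye-camera rate.
#' @param eye_h horizontal eye position (deg).
#' @param peak_times flow peak times (s).
#' @param blink_mask optional logical (TRUE = blink).
#' @param rate_hz eye sampling rate.
#' @param window_samples total samples per segment.
#' @param min_valid minimum valid samples to accept a segment.
#' @return List of `okn_segment`s: `peak_t`, `samples`, `n_valid`.
#' @export
extract_okn_segments <- function(t, eye_h, peak_times, blink_mask = NULL,
                                 rate_hz = 50, window_samples = 100,
                                 min_valid = 60) {
  half <- window_samples %/% 2
  segs <- list()
  valid0 <- is.finite(eye_h) & !(if (is.null(blink_mask)) FALSE else blink_mask)
  for (pt in peak_times) {
    ci <- which.min(abs(t - pt))
    i0 <- ci - half + 1L; i1 <- ci + (window_samples - half)
    if (i0 < 1 || i1 > length(t)) next
    v <- eye_h[i0:i1]
    ok <- valid0[i0:i1]
    if (sum(ok) < min_valid) next
    v[!ok] <- NA
    v <- linear_interp_na(v)
    segs[[length(segs) + 1L]] <- structure(
      list(peak_t = pt, samples = v, n_valid = sum(ok), rate_hz = rate_hz),
      class = "okn_segment")
  }
  segs
}

linear_interp_na <- function(v) {
  bad <- !is.finite(v)
  if (!any(bad)) return(v)
  idx <- seq_along(v)
  v[bad] <- stats::approx(idx[!bad], v[!bad], xout = idx[bad], rule = 2)$y
  v
}

#' Amplitude and dominant frequency of an OKN segment
#'
#' Linear detrend, Fourier transform, then the mean spectral amplitude and
#' the frequency of maximum amplitude restricted to the nystagmus band
#' (2-6 Hz; the lowest frequency wins ties). If the overall spectral peak
#' lies outside the band the result is flagged low-confidence.
#'
#' @param segment an `okn_segment` (or numeric vector at `rate_hz`).
#' @param rate_hz sampling rate, taken from the segment if available.
#' @param band frequency band (Hz).
#' @return List: `amplitude` (mean in-band spectral amplitude),
#'   `freq_hz` (in-band peak), `low_confidence`.
#' @export
okn_amplitude_frequency <- function(segment, rate_hz = 50, band = c(2, 6)) {
  if (inherits(segment, "okn_segment")) {
    v <- segment$samples
    rate_hz <- segment$rate_hz
  } else v <- segment
  n <- length(v)
  idx <- seq_len(n)
  v <- stats::resid(stats::lm(v ~ idx))
  amp <- Mod(stats::fft(v)) / n * 2
  freq <- (idx - 1) * rate_hz / n
  half <- freq <= rate_hz / 2
  amp_h <- amp[half]; freq_h <- freq[half]
  inb <- freq_h >= band[1] & freq_h <= band[2]
  i_best <- which(inb)[which.max(amp_h[inb])]   # which.max = lowest on ties
  peak_all <- freq_h[freq_h > 0][which.max(amp_h[freq_h > 0])]
  list(amplitude = mean(amp_h[inb]), freq_hz = freq_h[i_best],
       low_confidence = !(peak_all >= band[1] && peak_all <= band[2]))
}
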