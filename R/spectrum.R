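#' Average spatial-frequency power spectrum of scene frames
#'
#' Each frame is Hann-windowed (to curb edge leakage), transformed with a
#' 2-D FFT, and its power is radially averaged in bins of
#' `bin_cdeg` cycles/degree; the per-frame spectra are then averaged over
#' frames. The radial frequency accounts for the anisotropic sampling
#' density: the frequency of pixel `(u, v)` is
#' `sqrt((u/ (w/ppd_h))^2 + (v/(h/ppd_v))^2)` cycles/degree.
#'
#' @param frames raw/numeric array `(h, w, n)` of 8-bit frames, or a
#'   `session_bundle` (its scene frames are used).
#' @param camera a [camera_model()]; taken from the session when `frames`
#'   is a session.
#' @param bin_cdeg radial bin width in cycles/degree.
#' @param frame_step analyse every `frame_step`-th frame.
#' @return A `spectrum_result` list: `freq_cdeg` (bin centres, ascending and
#'   below the Nyquist limit `min(ppd)/2`), `log10_power` (log10 of the mean
#'   power per bin) and `n_frames`.
#' @export
average_power_spectrum <- function(frames, camera = NULL, bin_cdeg = 0.05,
                                   frame_step = 1L) {
  if (inherits(frames, "session_bundle")) {
    camera <- frames$camera
    frames <- frames$scene_frames
  }
  if (is.null(camera)) stop("camera model required")
  d <- dim(frames)
  h <- d[1]; w <- d[2]; n <- d[3]
  ppd_h <- w / camera$scene_fov_deg[1]
  ppd_v <- h / camera$scene_fov_deg[2]
  # per-pixel radial frequency in cycles/deg (FFT layout, two-sided)
  fu <- c(0:(floor(w / 2)), -(ceiling(w / 2) - 1):-1) / w * ppd_h
  fv <- c(0:(floor(h / 2)), -(ceiling(h / 2) - 1):-1) / h * ppd_v
  fr <- sqrt(outer(fv^2, fu^2, "+"))
  nyq <- min(ppd_h, ppd_v) / 2
  bin <- pmin(as.integer(floor(fr / bin_cdeg)),
              as.integer(floor(nyq / bin_cdeg)))
  win <- outer(hann(h), hann(w))
  sel <- seq(1, n, by = frame_step)
  acc <- NULL
  for (i in sel) {
    m <- frames[, , i]
    storage.mode(m) <- "integer"
    p <- Mod(stats::fft(m / 255 * win))^2
    s <- rowsum(as.vector(p), as.vector(bin))
    acc <- if (is.null(acc)) s else acc + s
  }
  counts <- tabulate(as.vector(bin) + 1L)[as.integer(rownames(acc)) + 1L]
  mean_power <- (acc / length(sel))[, 1] / counts
  freq <- (as.numeric(rownames(acc)) + 0.5) * bin_cdeg
  keep <- freq <= nyq
  out <- list(freq_cdeg = freq[keep], log10_power = log10(mean_power[keep]),
              n_frames = length(sel))
  class(out) <- "spectrum_result"
  out
}

# periodic Hann window (exact 3-coefficient DFT support)
hann <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)
}

#' Write a spectrum as CSV (freq, log10_power)
#' @param spec a `spectrum_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spec, path) {
  utils::write.csv(data.frame(freq_cdeg = spec$freq_cdeg,
                              log10_power = spec$log10_power),
                   path, row.names = FALSE)
  invisible(path)
}
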