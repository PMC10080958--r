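#' Gaze-centred luminance matrix
#'
#' Builds the luminance matrix `L(s, t)`: for every retained scene frame
#' (frames whose time falls inside a fixation or smooth-pursuit interval --
#' the epochs of stable retinal projection), each retinal offset is
#' converted to pixels through the per-axis sampling density, added to the
#' gaze pixel position, and the 8-bit intensity / 255 is stored. Offsets
#' landing outside the frame are flagged invalid for that frame; frames
#' where the gaze point itself is invalid or outside the scene are dropped
#' entirely.
#'
#' @param session a `session_bundle`.
#' @param offsets a `retinal_offsets` sample (see [draw_region_offsets()]).
#' @param labels a data.frame of labelled intervals with columns `start_s`,
#'   `end_s`, `label` (see [classify_segments()]), or `NULL` to retain every
#'   frame with valid gaze.
#' @param redraw_per_frame if `TRUE`, a fresh offset sample is drawn for
#'   every frame (only meaningful for purely spatial statistics; temporal
#'   statistics require the default fixed offsets).
#' @return A `luminance_matrix`: list with `L` (`n_offsets x n_frames`
#'   matrix in `[0,1]`), `valid` mask, `frame_times`, `frame_index`,
#'   `region`.
#' @export
gaze_centered_luminance <- function(session, offsets, labels = NULL,
                                    redraw_per_frame = FALSE) {
  stopifnot(inherits(session, "session_bundle"),
            inherits(offsets, "retinal_offsets"))
  cam <- session$camera
  d <- dim(session$scene_frames)
  h <- d[1]; w <- d[2]
  # effective px/deg for the stored frames (may be a downscaled stack)
  ppd_h <- w / cam$scene_fov_deg[1]
  ppd_v <- h / cam$scene_fov_deg[2]

  ft <- scene_frame_times(session)
  g <- session$gaze
  gi <- align_nearest(ft, g$t)
  ok <- g$validity[gi]
  gx <- g$gp[gi, 1] * w
  gy <- g$gp[gi, 2] * h
  ok <- ok & is.finite(gx) & is.finite(gy) &
    gx >= 1 & gx <= w & gy >= 1 & gy <= h
  if (!is.null(labels)) {
    keep <- in_any_interval(ft, labels[labels$label %in%
                                         c("fixation", "smooth_pursuit"), ,
                                       drop = FALSE])
    ok <- ok & keep
  }
  retained <- which(ok)
  if (!length(retained)) stop("no fixation/pursuit epochs with valid gaze")

  n_s <- offsets$n
  n_t <- length(retained)
  L <- matrix(NA_real_, n_s, n_t)
  valid <- matrix(FALSE, n_s, n_t)
  off <- offsets$offsets
  for (j in seq_len(n_t)) {
    fi <- retained[j]
    if (redraw_per_frame)
      off <- draw_region_offsets(offsets$region, n_s,
                                 seed = offsets$seed + j)$offsets
    px <- as.integer(round(gx[fi] + off[, 1] * ppd_h))
    py <- as.integer(round(gy[fi] + off[, 2] * ppd_v))
    inb <- px >= 1L & px <= w & py >= 1L & py <= h
    if (any(inb)) {
      idx <- (fi - 1L) * (h * w) + (px[inb] - 1L) * h + py[inb]
      vals <- as.integer(session$scene_frames[idx])
      L[inb, j] <- vals / 255
      valid[inb, j] <- TRUE
    }
  }
  out <- list(L = L, valid = valid, frame_times = ft[retained],
              frame_index = retained, region = offsets$region,
              n_s = n_s, n_t = n_t)
  class(out) <- "luminance_matrix"
  out
}

in_any_interval <- function(t, intervals) {
  keep <- rep(FALSE, length(t))
  if (is.null(intervals) || nrow(intervals) == 0) return(keep)
  for (k in seq_len(nrow(intervals)))
    keep <- keep | (t >= intervals$start_s[k] & t <= intervals$end_s[k])
  keep
}

#' Aperture luminance profiles
#'
#' One gaze-centred luminance matrix per circular aperture diameter,
#' supporting the centre-size gradient analysis (how contrast and skewness
#' change as the analysed central area grows from foveal to full-field
#' scale). Each aperture gets its own offset sample of size `n`.
#'
#' @param session a `session_bundle`.
#' @param labels interval labels (see [gaze_centered_luminance()]).
#' @param diameters_deg ascending aperture diameters in degrees.
#' @param n offsets per aperture.
#' @param seed base RNG seed; aperture `i` uses `seed + i`.
#' @return Named list of `luminance_matrix` objects (names = diameters).
#' @export
aperture_profile <- function(session, labels = NULL,
                             diameters_deg = c(5, 10, 15, 20, 25, 30, 60),
                             n = 1000, seed = 1) {
  if (is.unsorted(diameters_deg, strictly = TRUE))
    stop("aperture diameters must be ascending")
  out <- lapply(seq_along(diameters_deg), function(i) {
    reg <- retinal_region("aperture", inner_diameter_deg = 0,
                          outer_diameter_deg = diameters_deg[i])
    offs <- draw_region_offsets(reg, n = n, seed = seed + i)
    gaze_centered_luminance(session, offs, labels)
  })
  names(out) <- as.character(diameters_deg)
  out
}
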