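#' Gaze stream
#'
#' Time-stamped gaze records from the eye tracker at the eye-camera rate
#' (50 Hz by default): 2-D gaze position `gp` in normalized scene-camera
#' coordinates (`[0,0]` top-left to `[1,1]` bottom-right), 3-D gaze point
#' `gp3` in millimetres relative to the glasses centre, and per-eye pupil
#' diameters in millimetres. Invalid samples (blinks, tracking loss) are
#' flagged, never dropped, so downstream stages can honour the gaps.
#'
#' @param t sample times in seconds, strictly increasing.
#' @param gp n x 2 matrix of normalized gaze positions.
#' @param gp3 n x 3 matrix of 3-D gaze points (mm; x right, y down, z depth).
#' @param pd_left,pd_right pupil diameters (mm).
#' @param validity logical vector; `FALSE` marks unusable samples.
#' @return A `gaze_stream` data container (list of parallel vectors).
#' @export
gaze_stream <- function(t, gp, gp3, pd_left = NULL, pd_right = NULL,
                        validity = NULL) {
  n <- length(t)
  gp <- matrix(as.numeric(gp), ncol = 2)
  gp3 <- matrix(as.numeric(gp3), ncol = 3)
  stopifnot(nrow(gp) == n, nrow(gp3) == n)
  if (is.null(pd_left)) pd_left <- rep(NA_real_, n)
  if (is.null(pd_right)) pd_right <- rep(NA_real_, n)
  if (is.null(validity)) validity <- rep(TRUE, n)
  check_monotone(t, "gaze")
  bad_gp <- validity & (gp[, 1] < 0 | gp[, 1] > 1 | gp[, 2] < 0 | gp[, 2] > 1 |
                          is.na(gp[, 1]) | is.na(gp[, 2]))
  validity[bad_gp] <- FALSE
  s <- list(t = as.numeric(t), gp = gp, gp3 = gp3,
            pd_left = as.numeric(pd_left), pd_right = as.numeric(pd_right),
            validity = as.logical(validity))
  class(s) <- "gaze_stream"
  s
}

#' Inertial (IMU) stream
#'
#' Linear acceleration (`ac`, m/s^2) and angular velocity (`gy`, deg/s)
#' sampled at the inertial rate (100 Hz). Gyroscope axes follow the head
#' convention: x = pitch (looking up/down), y = yaw (left/right),
#' z = roll (head tilt).
#'
#' @param t sample times in seconds, strictly increasing.
#' @param ac n x 3 matrix of accelerations.
#' @param gy n x 3 matrix of angular velocities.
#' @return An `imu_stream` container.
#' @export
imu_stream <- function(t, ac, gy) {
  n <- length(t)
  ac <- matrix(as.numeric(ac), ncol = 3)
  gy <- matrix(as.numeric(gy), ncol = 3)
  stopifnot(nrow(ac) == n, nrow(gy) == n)
  check_monotone(t, "imu")
  s <- list(t = as.numeric(t), ac = ac, gy = gy)
  class(s) <- "imu_stream"
  s
}

check_monotone <- function(t, what) {
  if (length(t) > 1) {
    bad <- which(diff(t) <= 0)
    if (length(bad))
      stop(sprintf("%s timestamps not strictly increasing at index %d",
                   what, bad[1] + 1L))
  }
  invisible(TRUE)
}

#' Convert a 3-D gaze point to visual angles
#'
#' Azimuth and elevation of the gaze direction relative to the optical axis,
#' computed as the arctangent of the ratio between image-plane distance and
#' visual depth distance. Positive azimuth is rightward; positive elevation
#' is downward (image y grows downward). Samples with non-positive depth are
#' returned as `NA` (invalid), not errors, so streams keep their length.
#'
#' @param gp3 numeric length-3 vector `(x, y, z)` in mm, or an n x 3 matrix.
#' @return For a vector input, a named numeric `(azimuth_deg,
#'   elevation_deg)`; for a matrix, an n x 2 matrix.
#' @examples
#' gaze_to_degrees(c(100, 0, 1000)) # 5.71 deg azimuth
#' @export
gaze_to_degrees <- function(gp3) {
  one <- is.null(dim(gp3))
  m <- matrix(as.numeric(gp3), ncol = 3)
  z <- m[, 3]
  bad <- !is.finite(z) | z <= 0
  az <- atan2(m[, 1], z) * 180 / pi
  el <- atan2(m[, 2], z) * 180 / pi
  az[bad] <- NA_real_
  el[bad] <- NA_real_
  out <- cbind(azimuth_deg = az, elevation_deg = el)
  if (one) out[1, ] else out
}
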