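#' Session bundle
#'
#' Aggregates one head-mounted recording: camera geometry, the scene and eye
#' frame stacks (8-bit grayscale), and the gaze and inertial streams, all on
#' a common clock whose origin is the first scene frame. Frame stacks are
#' raw (one byte per pixel) arrays of dimension `(height, width, n_frames)`.
#'
#' @param camera a [camera_model()].
#' @param scene_frames raw array `(h, w, n)` of scene frames (may differ from
#'   the camera's native resolution for desk-scale work; the effective
#'   pixels-per-degree is rescaled accordingly).
#' @param eye_frames raw array `(h, w, n)` of eye frames.
#' @param gaze a [gaze_stream()].
#' @param imu an [imu_stream()].
#' @param task_label free-text task name (e.g. `"reading"`, `"walking"`).
#' @param duration_s session length in seconds.
#' @return A `session_bundle`.
#' @export
session_bundle <- function(camera, scene_frames, eye_frames, gaze, imu,
                           task_label = "", duration_s = NULL) {
  stopifnot(inherits(camera, "camera_model"),
            inherits(gaze, "gaze_stream"),
            inherits(imu, "imu_stream"))
  scene_frames <- as_frame_stack(scene_frames)
  eye_frames <- as_frame_stack(eye_frames)
  if (is.null(duration_s))
    duration_s <- dim(scene_frames)[3] / camera$scene_rate_hz
  s <- list(camera = camera, scene_frames = scene_frames,
            eye_frames = eye_frames, gaze = gaze, imu = imu,
            task_label = as.character(task_label),
            duration_s = as.numeric(duration_s))
  class(s) <- "session_bundle"
  validate_session(s)
  s
}

as_frame_stack <- function(x) {
  if (is.raw(x) && length(dim(x)) == 3) return(x)
  if (is.numeric(x) && length(dim(x)) == 3) {
    v <- as.integer(round(x))
    if (any(v < 0L | v > 255L, na.rm = TRUE)) stop("frame values must be 0..255")
    r <- as.raw(v)
    dim(r) <- dim(x)
    return(r)
  }
  stop("frames must be a (h, w, n) array of raw or 0..255 values")
}

#' Validate internal consistency of a session
#'
#' Checks frame counts against `duration x rate` (within one frame), stream
#' monotonicity, and that all streams cover a common time interval.
#'
#' @param session a `session_bundle`.
#' @return The session, invisibly; errors describe the first inconsistency.
#' @export
validate_session <- function(session) {
  cam <- session$camera
  n_scene <- dim(session$scene_frames)[3]
  n_eye <- dim(session$eye_frames)[3]
  dur <- session$duration_s
  if (abs(n_scene - dur * cam$scene_rate_hz) > 1)
    stop(sprintf("scene frame count %d inconsistent with %.1f s @ %g Hz",
                 n_scene, dur, cam$scene_rate_hz))
  if (abs(n_eye - dur * cam$eye_rate_hz) > 1)
    stop(sprintf("eye frame count %d inconsistent with %.1f s @ %g Hz",
                 n_eye, dur, cam$eye_rate_hz))
  check_monotone(session$gaze$t, "gaze")
  check_monotone(session$imu$t, "imu")
  # every stream must span (most of) the scene-frame interval
  t_end <- (n_scene - 1) / cam$scene_rate_hz
  for (nm in c("gaze", "imu")) {
    tt <- session[[nm]]$t
    if (length(tt) == 0) stop(nm, " stream is empty")
    if (tt[1] > 0.5 || tt[length(tt)] < t_end - 0.5)
      stop(nm, " stream does not cover the scene-frame interval")
  }
  invisible(session)
}

#' Scene frame timestamps (seconds, clock origin at the first frame)
#' @param session a `session_bundle`.
#' @return Numeric vector, one time per scene frame.
#' @export
scene_frame_times <- function(session) {
  (seq_len(dim(session$scene_frames)[3]) - 1) / session$camera$scene_rate_hz
}

#' Eye frame timestamps (seconds)
#' @param session a `session_bundle`.
#' @return Numeric vector, one time per eye frame.
#' @export
eye_frame_times <- function(session) {
  (seq_len(dim(session$eye_frames)[3]) - 1) / session$camera$eye_rate_hz
}

# one frame as numeric matrix in [0, 1]
frame_luminance <- function(frames, i) {
  m <- frames[, , i]
  storage.mode(m) <- "integer"
  m / 255
}

# nearest-neighbour index of each query time in a reference time grid
align_nearest <- function(t_query, t_ref) {
  idx <- findInterval(t_query, t_ref)
  idx[idx < 1L] <- 1L
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(t_ref))
  use_hi <- abs(t_ref[hi] - t_query) < abs(t_query - t_ref[lo])
  ifelse(use_hi, hi, lo)
}

#' Convert an RGB frame to 8-bit grayscale luminance
#'
#' ITU-R BT.601 weighted sum (0.299 R + 0.587 G + 0.114 B) with
#' round-half-up to 8 bits. Pixel intensity is treated as proportional to
#' scene luminance (the scene camera's luminance/intensity relation is
#' close to linear); pass the result through a gamma hook first if a
#' calibrated linearization is available.
#'
#' @param rgb_frame numeric or integer array `(h, w, 3)` with values 0..255.
#' @return Integer matrix `(h, w)` of gray levels 0..255.
#' @examples
#' px <- array(0, c(1, 1, 3)); px[1, 1, 1] <- 255
#' luminance_image(px) # pure red -> 76
#' @export
luminance_image <- function(rgb_frame) {
  d <- dim(rgb_frame)
  if (length(d) != 3 || d[3] != 3)
    stop("expected a 3-channel (h, w, 3) frame, got dims: ",
         paste(d, collapse = "x"))
  y <- 0.299 * rgb_frame[, , 1] + 0.587 * rgb_frame[, , 2] +
    0.114 * rgb_frame[, , 3]
  out <- as.integer(floor(y + 0.5))
  out[out > 255L] <- 255L
  out[out < 0L] <- 0L
  dim(out) <- d[1:2]
  out
}
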