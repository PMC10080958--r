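#' Head-mounted camera geometry
#'
#' Describes the fixed geometry and sampling rates of the head-mounted
#' recording device: a wide-angle scene camera, paired infrared eye cameras,
#' and an inertial measurement unit. Defaults match the vendor glasses used
#' in indoor reading/walking recordings: an 82 x 52 degree scene field of
#' view imaged at 1,920 x 1,080 pixels and 25 Hz, eye videos of 240 x 960
#' pixels at 50 Hz, and inertial sampling at 100 Hz.
#'
#' @param scene_fov_deg numeric length-2, horizontal and vertical field of
#'   view of the scene camera in degrees.
#' @param scene_resolution_px integer length-2, scene image width and height
#'   in pixels.
#' @param scene_rate_hz scene camera frame rate (Hz).
#' @param eye_resolution_px integer length-2, eye image width and height.
#' @param eye_rate_hz eye camera frame rate (Hz).
#' @param imu_rate_hz inertial sensor sampling rate (Hz).
#' @return An object of class `camera_model` with a `ppd` field holding the
#'   horizontal and vertical sampling densities in pixels per degree.
#' @examples
#' cam <- camera_model()
#' round(cam$ppd) # 23 horizontal, 21 vertical
#' @export
camera_model <- function(scene_fov_deg = c(82, 52),
                         scene_resolution_px = c(1920, 1080),
                         scene_rate_hz = 25,
                         eye_resolution_px = c(240, 960),
                         eye_rate_hz = 50,
                         imu_rate_hz = 100) {
  stopifnot(length(scene_fov_deg) == 2, all(scene_fov_deg > 0),
            length(scene_resolution_px) == 2, all(scene_resolution_px > 0))
  if (scene_rate_hz <= 0 || eye_rate_hz <= 0 || imu_rate_hz <= 0)
    stop("all sampling rates must be > 0")
  cam <- list(
    scene_fov_deg = as.numeric(scene_fov_deg),
    scene_resolution_px = as.integer(scene_resolution_px),
    scene_rate_hz = as.numeric(scene_rate_hz),
    eye_resolution_px = as.integer(eye_resolution_px),
    eye_rate_hz = as.numeric(eye_rate_hz),
    imu_rate_hz = as.numeric(imu_rate_hz),
    ppd = as.numeric(scene_resolution_px) / as.numeric(scene_fov_deg)
  )
  class(cam) <- "camera_model"
  cam
}

#' Scene-camera sampling density
#'
#' Pixels per degree of visual angle along one image axis: the axis
#' resolution divided by its field of view. For the default camera this is
#' 1920/82 = 23.4 px/deg horizontally (23 to the nearest integer) and
#' 1080/52 = 20.8 px/deg vertically (21).
#'
#' @param camera a [camera_model()].
#' @param axis `"horizontal"` or `"vertical"`.
#' @return Sampling density in pixels per degree (not rounded; use
#'   `round()` for the conventional integer display value).
#' @export
pixels_per_degree <- function(camera, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  i <- if (axis == "horizontal") 1L else 2L
  camera$scene_resolution_px[i] / camera$scene_fov_deg[i]
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("camera_model: scene %dx%d px, %gx%g deg (%.1f/%.1f px/deg) @ %g Hz\n",
              x$scene_resolution_px[1], x$scene_resolution_px[2],
              x$scene_fov_deg[1], x$scene_fov_deg[2],
              x$ppd[1], x$ppd[2], x$scene_rate_hz))
  cat(sprintf("  eyes %dx%d px @ %g Hz, imu @ %g Hz\n",
              x$eye_resolution_px[1], x$eye_resolution_px[2],
              x$eye_rate_hz, x$imu_rate_hz))
  invisible(x)
}
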