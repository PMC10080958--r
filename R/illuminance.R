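#' Retinal illuminance in trolands
#'
#' Retinal illuminance is the product of stimulus luminance and pupil
#' area: `T = L_v * pi * (d/2)^2`, with luminance in cd/m^2 and pupil
#' diameter in mm. Reference points for indoor tasks: a 2 cd/m^2 black
#' monitor background with a 4.24 mm pupil gives ~28 td, a 90 cd/m^2 white
#' page with a 3.70 mm pupil ~968 td, and a 9,500 cd/m^2 bright sky with a
#' 2.09 mm pupil ~3.3e4 td -- illustrating the orders of magnitude
#' separating reading from outdoor viewing.
#'
#' @param luminance_cdm2 luminance in candela per square metre.
#' @param pupil_diameter_mm pupil diameter in millimetres.
#' @return Retinal illuminance in trolands (vectorized over inputs).
#' @examples
#' retinal_illuminance_trolands(2, 4.24)
#' @export
retinal_illuminance_trolands <- function(luminance_cdm2, pupil_diameter_mm) {
  if (any(!is.finite(luminance_cdm2)) || any(!is.finite(pupil_diameter_mm)) ||
      any(luminance_cdm2 <= 0) || any(pupil_diameter_mm <= 0))
    stop("luminance and pupil diameter must be positive")
  luminance_cdm2 * pi * (pupil_diameter_mm / 2)^2
}

#' Half-range crossing eccentricity of an aperture profile
#'
#' Given a metric measured at a series of aperture diameters, returns the
#' diameter at which the metric first reaches 50% of its min-to-max range,
#' by linear interpolation between the bracketing apertures. Used to
#' summarize how far into the visual field a centre-periphery gradient
#' extends. A constant (non-crossing) profile is undefined and returns
#' `NA` with a warning.
#'
#' @param diameters_deg ascending aperture diameters (degrees), length >= 3.
#' @param metric_values metric at each diameter (finite).
#' @return Interpolated crossing diameter in degrees, or `NA` if the metric
#'   never crosses its half range.
#' @export
half_range_eccentricity <- function(diameters_deg, metric_values) {
  stopifnot(length(diameters_deg) >= 3,
            length(metric_values) == length(diameters_deg))
  if (any(!is.finite(metric_values))) stop("metric values must be finite")
  lo <- min(metric_values); hi <- max(metric_values)
  if (hi == lo) {
    warning("constant metric: half-range eccentricity undefined")
    return(NA_real_)
  }
  target <- lo + 0.5 * (hi - lo)
  side <- metric_values >= target
  for (i in seq_along(side)[-1]) {
    if (side[i] != side[1]) {        # first crossing wins
      x0 <- diameters_deg[i - 1]; x1 <- diameters_deg[i]
      y0 <- metric_values[i - 1]; y1 <- metric_values[i]
      return(x0 + (target - y0) / (y1 - y0) * (x1 - x0))
    }
  }
  if (side[1] && metric_values[1] == target) return(diameters_deg[1])
  warning("metric does not cross its half range")
  NA_real_
}
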