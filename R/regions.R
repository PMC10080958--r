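#' Retinal region specification
#'
#' Gaze-centred circular or annular regions of the visual field, in degrees
#' of visual angle. Built-in named regions follow the operational
#' definitions used for analyzing head-mounted recordings: the fovea is a
#' 5-degree-diameter disc centred at the gaze point; the periphery is the
#' ring between the parafovea and the far periphery, with inner and outer
#' diameters of 8 and 60 degrees; `periphery_upper` / `periphery_lower`
#' restrict the ring to one half of the visual field. `aperture` regions
#' are discs of arbitrary diameter used for the centre-size gradient
#' analysis.
#'
#' The `"upper"` visual half has negative vertical offsets because image
#' coordinates grow downward; configure `half` explicitly for other
#' conventions.
#'
#' @param name one of `"fovea"`, `"periphery"`, `"periphery_upper"`,
#'   `"periphery_lower"`, `"aperture"`.
#' @param inner_diameter_deg,outer_diameter_deg annulus diameters (degrees);
#'   defaults follow the named region.
#' @param half `"none"`, `"upper"` or `"lower"`.
#' @return A `retinal_region` spec.
#' @export
retinal_region <- function(name = c("fovea", "periphery", "periphery_upper",
                                    "periphery_lower", "aperture"),
                           inner_diameter_deg = NULL,
                           outer_diameter_deg = NULL,
                           half = NULL) {
  name <- match.arg(name)
  defaults <- switch(name,
    fovea = list(0, 5, "none"),
    periphery = list(8, 60, "none"),
    periphery_upper = list(8, 60, "upper"),
    periphery_lower = list(8, 60, "lower"),
    aperture = list(0, 60, "none"))
  if (is.null(inner_diameter_deg)) inner_diameter_deg <- defaults[[1]]
  if (is.null(outer_diameter_deg)) outer_diameter_deg <- defaults[[2]]
  if (is.null(half)) half <- defaults[[3]]
  half <- match.arg(half, c("none", "upper", "lower"))
  if (!(inner_diameter_deg >= 0 && inner_diameter_deg < outer_diameter_deg))
    stop("region requires 0 <= inner < outer diameter")
  r <- list(name = name, inner_diameter_deg = inner_diameter_deg,
            outer_diameter_deg = outer_diameter_deg, half = half)
  class(r) <- "retinal_region"
  r
}

#' Draw the fixed pixel-offset sample for a retinal region
#'
#' Randomly selects `n` gaze-relative offsets (default 1,000) uniformly by
#' area over the region, in degree coordinates. Sampling in degree space
#' (not pixel space) keeps eccentricity coverage unbiased under anisotropic
#' pixels-per-degree. The offsets are drawn once per region per analysis
#' and reused for every frame, so a given column of the luminance matrix
#' always refers to the same retinal location -- a requirement for the
#' temporal statistics.
#'
#' @param region a [retinal_region()].
#' @param n number of offsets.
#' @param seed RNG seed (deterministic sample for a given seed).
#' @return A `retinal_offsets` object with an `offsets` (n x 2) matrix of
#'   `(d_h_deg, d_v_deg)` pairs.
#' @export
draw_region_offsets <- function(region, n = 1000, seed = 1) {
  stopifnot(inherits(region, "retinal_region"), n >= 1)
  r0 <- region$inner_diameter_deg / 2
  r1 <- region$outer_diameter_deg / 2
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ecc <- sqrt(stats::runif(n, r0^2, r1^2))
  theta <- switch(region$half,
    none = stats::runif(n, 0, 2 * pi),
    upper = stats::runif(n, pi, 2 * pi),  # sin(theta) < 0: d_v < 0
    lower = stats::runif(n, 0, pi))
  off <- cbind(d_h_deg = ecc * cos(theta), d_v_deg = ecc * sin(theta))
  out <- list(offsets = off, n = as.integer(n), seed = seed, region = region)
  class(out) <- "retinal_offsets"
  out
}

#' Export a region offset sample as CSV
#' @param offsets a `retinal_offsets` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_offsets_csv <- function(offsets, path) {
  df <- data.frame(offset_index = seq_len(offsets$n),
                   d_h_deg = offsets$offsets[, 1],
                   d_v_deg = offsets$offsets[, 2])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
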