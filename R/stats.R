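#' Root-mean-square contrast of a luminance matrix
#'
#' RMS deviation of luminance from its mean, the standard contrast measure
#' for natural stimuli. Along `axis = "space"` the statistic is computed per
#' retained frame `t` over offsets `s` (spatial contrast `C_S(t)`); along
#' `axis = "time"` per offset `s` over frames (temporal contrast `C_T(s)`).
#' The sum of squared deviations is divided by `N - 1`, with `N` the number
#' of valid cells in that row/column (cells flagged invalid by the sampler
#' are excluded). Rows/columns with fewer than 2 valid cells are `NA`.
#'
#' @param L a `luminance_matrix` (or a plain numeric matrix, offsets in
#'   rows, frames in columns; all cells then count as valid).
#' @param axis `"space"` or `"time"`.
#' @return Numeric vector of contrasts (per frame for `"space"`, per offset
#'   for `"time"`), with a `low_confidence` attribute marking entries
#'   computed from fewer than 30 valid cells.
#' @export
rms_contrast <- function(L, axis = c("space", "time")) {
  axis <- match.arg(axis)
  lm <- as_lum_matrix(L)
  moment_stat(lm, axis, function(x, n, mu) sqrt(sum((x - mu)^2) / (n - 1)),
              min_n = 2L)
}

#' Luminance skewness of a luminance matrix
#'
#' Third standardized moment of the luminance distribution: the deviation
#' of each luminance value from the mean, normalized by the RMS contrast,
#' cubed, and averaged (divisor `N`, the valid count -- note this
#' intentionally differs from the `N - 1` divisor inside the contrast).
#' Negative skewness means the variation is dominated by dark pixels
#' (OFF-pathway-weighted stimulation), positive by light pixels
#' (ON-pathway-weighted). Rows/columns whose contrast is zero (constant
#' luminance) are undefined and returned as `NA`.
#'
#' @inheritParams rms_contrast
#' @return Numeric vector of skewness values (per frame for `"space"`, per
#'   offset for `"time"`), with a `low_confidence` attribute as in
#'   [rms_contrast()].
#' @export
luminance_skewness <- function(L, axis = c("space", "time")) {
  axis <- match.arg(axis)
  lm <- as_lum_matrix(L)
  moment_stat(lm, axis, function(x, n, mu) {
    C <- sqrt(sum((x - mu)^2) / (n - 1))
    if (!is.finite(C) || C == 0) return(NA_real_)
    sum(((x - mu) / C)^3) / n
  }, min_n = 2L)
}

#' Mean pixel intensity
#'
#' Arithmetic mean of the valid luminance samples: per retained frame and
#' as a grand mean over all valid cells. Values are in `[0, 1]` (8-bit
#' intensity / 255).
#'
#' @inheritParams rms_contrast
#' @return List with `per_frame` (numeric vector) and `grand_mean`.
#' @export
mean_pixel_intensity <- function(L) {
  lm <- as_lum_matrix(L)
  x <- lm$L
  x[!lm$valid] <- NA
  per_frame <- colMeans(x, na.rm = TRUE)
  per_frame[colSums(lm$valid) == 0] <- NA_real_
  list(per_frame = per_frame,
       grand_mean = mean(x, na.rm = TRUE))
}

#' All spatiotemporal statistics of one luminance matrix
#'
#' Convenience wrapper computing spatial/temporal contrast, skewness and
#' mean in one pass, plus `mean +/- sd` summaries over the per-frame and
#' per-offset arrays (the form in which the statistics are conventionally
#' reported).
#'
#' @inheritParams rms_contrast
#' @return A `spatiotemporal_stats` list: `C_S`, `C_T`, `SK_S`, `SK_T`,
#'   `mu_S`, `mu_T`, and a `summary` data.frame (metric, mean, sd, n).
#' @export
spatio_temporal_stats <- function(L) {
  lm <- as_lum_matrix(L)
  x <- lm$L; x[!lm$valid] <- NA
  res <- list(
    C_S = rms_contrast(lm, "space"),
    C_T = rms_contrast(lm, "time"),
    SK_S = luminance_skewness(lm, "space"),
    SK_T = luminance_skewness(lm, "time"),
    mu_S = colMeans(x, na.rm = TRUE),
    mu_T = rowMeans(x, na.rm = TRUE))
  summ <- do.call(rbind, lapply(names(res), function(nm) {
    v <- res[[nm]][is.finite(res[[nm]])]
    data.frame(metric = nm, mean = mean(v), sd = stats::sd(v), n = length(v))
  }))
  res$summary <- summ
  class(res) <- "spatiotemporal_stats"
  res
}

as_lum_matrix <- function(L) {
  if (inherits(L, "luminance_matrix")) return(L)
  if (is.matrix(L))
    return(list(L = L, valid = is.finite(L),
                n_s = nrow(L), n_t = ncol(L)))
  stop("expected a luminance_matrix or numeric matrix")
}

# apply f(x, n, mu) along rows (time) or columns (space) of the valid cells
moment_stat <- function(lm, axis, f, min_n = 2L) {
  x <- lm$L
  x[!lm$valid] <- NA
  if (axis == "space") {
    vals <- apply(x, 2, stat_one, f = f, min_n = min_n)
  } else {
    vals <- apply(x, 1, stat_one, f = f, min_n = min_n)
  }
  ns <- if (axis == "space") colSums(lm$valid) else rowSums(lm$valid)
  attr(vals, "low_confidence") <- ns < 30L
  vals
}

stat_one <- function(col, f, min_n) {
  v <- col[is.finite(col)]
  n <- length(v)
  if (n < min_n) return(NA_real_)
  f(v, n, mean(v))
}

#' Write per-frame / per-offset statistics tables as CSV
#'
#' @param stats a `spatiotemporal_stats` object.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix (e.g. region name).
#' @return Paths of the files written, invisibly.
#' @export
write_stats_csv <- function(stats, dir, prefix = "region") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pf <- file.path(dir, paste0(prefix, "_per_frame.csv"))
  po <- file.path(dir, paste0(prefix, "_per_offset.csv"))
  ps <- file.path(dir, paste0(prefix, "_summary.csv"))
  utils::write.csv(data.frame(t = seq_along(stats$C_S), C_S = stats$C_S,
                              SK_S = stats$SK_S, mu_S = stats$mu_S),
                   pf, row.names = FALSE)
  utils::write.csv(data.frame(s = seq_along(stats$C_T), C_T = stats$C_T,
                              SK_T = stats$SK_T, mu_T = stats$mu_T),
                   po, row.names = FALSE)
  utils::write.csv(stats$summary, ps, row.names = FALSE)
  invisible(c(pf, po, ps))
}
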