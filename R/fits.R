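#' Fit a Gaussian curve to (x, y) data
#'
#' Least-squares fit of `y = b + a * exp(-(x - mu)^2 / (2 sigma^2))`, the
#' model used for symmetric parameter distributions (e.g. contrast
#' histograms during walking). Initialization comes from histogram moments
#' (baseline = min, amplitude = range, mean = arg-max, sigma from the
#' half-maximum width), refined with bounded L-BFGS-B and a fixed
#' iteration cap. Goodness of fit is the coefficient of determination R^2
#' on the fitted curve.
#'
#' @param x,y numeric vectors (>= 4 points).
#' @param maxit iteration cap for the optimizer.
#' @return A `gaussian_fit` list: `b`, `a`, `mu`, `sigma` (> 0), `r2`,
#'   `converged`.
#' @export
fit_gaussian <- function(x, y, maxit = 500) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  b0 <- min(y); a0 <- max(y) - b0
  mu0 <- x[which.max(y)]
  above <- x[y >= b0 + a0 / 2]
  s0 <- max((max(above) - min(above)) / 2.355, diff(range(x)) / 100)
  fn <- function(p) sum((y - (p[1] + p[2] * exp(-(x - p[3])^2 / (2 * p[4]^2))))^2)
  xr <- diff(range(x))
  res <- stats::optim(c(b0, a0, mu0, s0), fn, method = "L-BFGS-B",
                      lower = c(b0 - 2 * abs(a0) - 1e-9, -Inf, min(x) - xr, xr * 1e-6),
                      upper = c(max(y) + 1e-9, Inf, max(x) + xr, xr * 10),
                      control = list(maxit = maxit, factr = 1e2))
  p <- res$par
  yhat <- p[1] + p[2] * exp(-(x - p[3])^2 / (2 * p[4]^2))
  out <- list(b = p[1], a = p[2], mu = p[3], sigma = abs(p[4]),
              r2 = r_squared(y, yhat), converged = res$convergence == 0)
  if (!out$converged)
    warning("gaussian fit did not converge: ", res$message)
  class(out) <- "gaussian_fit"
  out
}

#' Fit an Alpha function to (x, y) data
#'
#' Least-squares fit of the skewed unimodal curve
#' `y = max(0, b + d * ((x - a)/r) * exp(1 - (x - a)/r))`, used for
#' asymmetric parameter distributions (e.g. temporal-contrast histograms
#' during reading, fixation-distance histograms during walking). The curve
#' rises from origin `a`, peaks at `x = a + r` with value `b + d`, and
#' decays exponentially; `r > 0` controls the rise and `d` the decay phase.
#' Initialization: `b` = min, `a` = first rise above 5% of range,
#' `r` = arg-max minus `a`, `d` = range.
#'
#' @param x,y numeric vectors (>= 5 points).
#' @param maxit iteration cap.
#' @return An `alpha_fit` list: `b`, `d`, `r` (> 0), `a`, `r2`, `converged`.
#' @export
fit_alpha <- function(x, y, maxit = 1000) {
  stopifnot(length(x) == length(y), length(x) >= 5)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  o <- order(x); x <- x[o]; y <- y[o]
  b0 <- min(y); rng <- max(y) - b0
  i_rise <- which(y > b0 + 0.05 * rng)[1]
  a0 <- if (is.na(i_rise) || i_rise == 1) x[1] else x[i_rise - 1]
  r0 <- max(x[which.max(y)] - a0, diff(range(x)) / 50)
  d0 <- rng
  fn <- function(p) sum((y - alpha_curve(x, p))^2)
  xr <- diff(range(x))
  res <- stats::optim(c(b0, d0, r0, a0), fn, method = "L-BFGS-B",
                      lower = c(-Inf, -Inf, xr * 1e-6, min(x) - 2 * xr),
                      upper = c(Inf, Inf, xr * 10, max(x) + xr),
                      control = list(maxit = maxit, factr = 1e2))
  p <- res$par
  out <- list(b = p[1], d = p[2], r = p[3], a = p[4],
              r2 = r_squared(y, alpha_curve(x, p)),
              converged = res$convergence == 0)
  if (!out$converged)
    warning("alpha fit did not converge: ", res$message)
  class(out) <- "alpha_fit"
  out
}

alpha_curve <- function(x, p) {
  z <- (x - p[4]) / p[3]
  pmax(0, p[1] + p[2] * z * exp(pmin(1 - z, 700)))  # clamp avoids Inf*0
}

r_squared <- function(y, yhat) {
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(if (ss_res == 0) 1 else 0)
  1 - ss_res / ss_tot
}
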