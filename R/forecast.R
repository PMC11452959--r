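# Forecasting fitted segmented trends to policy horizons with
# simulation-based 95% intervals.
#
# Interval construction: the AR(1) coefficient is integrated out rather than
# fixed at its (small-sample biased) point estimate. rho is drawn from its
# restricted-likelihood weights on a grid over (-0.98, 0.98); given rho the
# trend value x'beta is univariate t with df = n - p, centred at the GLS
# estimate with the GLS scale at that rho. Empirical quantiles over the
# draws give the interval. Conditioning on rho-hat alone materially
# understates forecast uncertainty at T = 30.

# Profile fits and restricted-likelihood weights over a rho grid.
.rho_grid_profiles <- function(fit, step = 0.02, bound = 0.98) {
  parts <- .ar1_parts(fit$y, fit$design)
  grid <- seq(-bound, bound, by = step)
  profs <- lapply(grid, .ar1_profile, parts = parts)
  df <- max(fit$nobs - length(fit$coefficients), 1L)
  llR <- vapply(seq_along(grid), function(i) {
    pr <- profs[[i]]
    s2R <- max(pr$rss / df, .Machine$double.xmin)
    -0.5 * df * (log(2 * pi * s2R) + 1) + 0.5 * log1p(-grid[i]^2) -
      0.5 * as.numeric(determinant(pr$XtX, logarithm = TRUE)$modulus)
  }, numeric(1))
  w <- exp(llR - max(llR))
  list(grid = grid, profs = profs, w = w / sum(w), df = df)
}

#' Predict from a segmented trend fit
#'
#' The point prediction at any year is the fitted piecewise linear mean; for
#' years beyond the data it is the final segment's line extrapolated.
#' Intervals are computed by seeded parametric simulation that propagates
#' both coefficient and autocorrelation uncertainty. With
#' `interval = "mean"` (the trend confidence interval, the default reported
#' interval) each draw first samples `rho` from its restricted-likelihood
#' weights on a grid, then the trend value from a t distribution
#' (`df = n - p`) centred at the GLS estimate with the GLS scale at that
#' `rho`; empirical `(1-level)/2` quantiles over the draws give the
#' interval. With `interval = "prediction"` an AR(1) error path is
#' additionally propagated from the last in-sample residual through the
#' horizon, giving an interval for a new observation.
#'
#' @param object A `segtrend` fit.
#' @param years Calendar years to predict at; defaults to the observed years.
#' @param interval `"none"`, `"mean"` or `"prediction"`.
#' @param level Interval coverage (default 0.95).
#' @param nsim Number of simulation draws.
#' @param seed Integer seed for the draws (RNG state restored afterwards).
#' @param ... Unused.
#' @return Data frame with columns `year`, `fit` and, when an interval is
#'   requested, `lwr` and `upr`.
#' @export
predict.segtrend <- function(object, years = NULL,
                             interval = c("none", "mean", "prediction"),
                             level = 0.95, nsim = 10000, seed = NULL, ...) {
  interval <- match.arg(interval)
  if (is.null(years)) years <- object$years
  years <- as.integer(years)
  Xh <- .design_at(object, years)
  point <- drop(Xh %*% object$coefficients)
  if (interval == "none")
    return(data.frame(year = years, fit = point))

  last_year <- max(object$years)
  if (interval == "prediction" && any(years <= last_year))
    abort_ncd("prediction intervals are only defined beyond the data end",
              "ncd_domain_error")

  gp <- .rho_grid_profiles(object)
  H <- length(years)
  G <- length(gp$grid)
  # per grid rho: trend means and scales at the requested years
  M <- matrix(vapply(gp$profs, function(pr) drop(Xh %*% pr$beta),
                     numeric(H)), H, G)
  S <- matrix(vapply(gp$profs, function(pr) {
    V <- (pr$rss / gp$df) * solve(pr$XtX)
    sqrt(pmax(rowSums((Xh %*% V) * Xh), 0))
  }, numeric(H)), H, G)
  draws <- with_seed(seed, {
    gi <- sample.int(G, nsim, replace = TRUE, prob = gp$w)
    scale <- sqrt(rchisq(nsim, gp$df) / gp$df)
    tdraw <- rnorm(nsim) / scale
    D <- M[, gi, drop = FALSE] +
      S[, gi, drop = FALSE] * matrix(tdraw, H, nsim, byrow = TRUE)
    if (interval == "prediction") {
      rho_b <- gp$grid[gi]
      sigma_b <- sqrt(vapply(gp$profs, function(pr) pr$rss / gp$df,
                             numeric(1))[gi]) / scale
      e_T <- object$residuals[object$nobs]
      steps <- max(years) - last_year
      E <- matrix(0, steps, nsim)
      prev <- rep(e_T, nsim)
      for (h in seq_len(steps)) {
        prev <- rho_b * prev + sigma_b * rnorm(nsim)
        E[h, ] <- prev
      }
      D <- D + E[years - last_year, , drop = FALSE]
    }
    D
  })
  qs <- t(apply(draws, 1L, quantile,
                probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                names = FALSE))
  data.frame(year = years, fit = point, lwr = qs[, 1L], upr = qs[, 2L])
}

#' Forecast a single horizon year with a 95% interval
#'
#' Thin wrapper around [predict.segtrend()] returning the point prediction
#' (the final-segment trend line at the horizon) and the simulation interval.
#'
#' @param fit A `segtrend` object.
#' @param horizon_year Calendar year strictly after the last observed year.
#' @param level Interval coverage.
#' @param nsim,seed Simulation settings; see [predict.segtrend()].
#' @param interval `"mean"` (trend interval, default) or `"prediction"`.
#' @return A one-row data frame with `horizon_year`, `point`, `lo`, `hi` and
#'   `method`.
#' @export
forecast_rate <- function(fit, horizon_year, level = 0.95, nsim = 10000,
                          seed = NULL, interval = c("mean", "prediction")) {
  interval <- match.arg(interval)
  stopifnot(inherits(fit, "segtrend"))
  if (horizon_year <= max(fit$years))
    abort_ncd("horizon_year must be after the last observed year",
              "ncd_domain_error")
  pr <- predict(fit, years = horizon_year, interval = interval,
                level = level, nsim = nsim, seed = seed)
  data.frame(horizon_year = horizon_year, point = pr$fit, lo = pr$lwr,
             hi = pr$upr, method = "segmented_ar1",
             stringsAsFactors = FALSE)
}
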