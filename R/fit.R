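# Piecewise linear trend fitting with AR(1) errors by exact Gaussian maximum
# likelihood, and AIC-based change-point search.
#
# Model: y = X beta + e,  e_t = rho e_{t-1} + eps_t,  eps_t ~ iid N(0, sigma2),
# with X the segmented design of build_segmented_design(). The likelihood is
# the exact stationary AR(1) Gaussian likelihood; beta and sigma2 are profiled
# out in closed form (Prais-Winsten transform) and rho is maximized
# numerically on (-1, 1).

# Precompute the crossproduct pieces from which the transformed normal
# equations are polynomial in rho:
#   Xs'Xs = (X1'X1 + U'U) - rho (U'V + V'U) + rho^2 (V'V - X1'X1)
# where X1 is the first row and U, V the lead/lag row blocks.
.ar1_parts <- function(y, X) {
  n <- length(y)
  X1 <- X[1L, , drop = FALSE]; U <- X[-1L, , drop = FALSE]
  V <- X[-n, , drop = FALSE]
  y1 <- y[1L]; yu <- y[-1L]; yv <- y[-n]
  UtV <- crossprod(U, V)
  list(n = n, p = ncol(X),
       A0 = crossprod(X1) + crossprod(U),
       A1 = UtV + t(UtV),
       A2 = crossprod(V) - crossprod(X1),
       b0 = crossprod(X1, y1) + crossprod(U, yu),
       b1 = crossprod(U, yv) + crossprod(V, yu),
       b2 = crossprod(V, yv) - crossprod(X1, y1),
       c0 = y1^2 + sum(yu^2), c1 = 2 * sum(yu * yv),
       c2 = sum(yv^2) - y1^2,
       # variance floor relative to the data scale: on exactly
       # piecewise-linear input the residual sum of squares is
       # floating-point noise, and without a common floor its random
       # magnitude (not parsimony) would drive AIC
       floor = 1e-10 * sum(y^2) / n)
}

# Profile log-likelihood (beta, sigma2 concentrated out) at a given rho.
.ar1_profile <- function(rho, parts) {
  XtX <- parts$A0 - rho * parts$A1 + rho^2 * parts$A2
  Xty <- parts$b0 - rho * parts$b1 + rho^2 * parts$b2
  yty <- parts$c0 - rho * parts$c1 + rho^2 * parts$c2
  beta <- tryCatch(solve(XtX, Xty),
                   error = function(e) abort_ncd(
                     "singular transformed design in AR(1) fit",
                     "ncd_design_error"))
  rss <- max(yty - sum(beta * Xty), 0)
  n <- parts$n
  sigma2 <- max(rss / n, parts$floor, .Machine$double.xmin)
  ll <- -0.5 * n * (log(2 * pi * sigma2) + 1) + 0.5 * log1p(-rho^2)
  list(loglik = ll, beta = drop(beta), sigma2 = sigma2, rss = rss, XtX = XtX)
}

# Maximize the profile likelihood in rho: coarse grid then local refinement.
.ar1_ml <- function(y, X, rho = NULL, rho_bound = 0.99) {
  parts <- .ar1_parts(y, X)
  if (!is.null(rho)) {
    prof <- .ar1_profile(rho, parts)
    return(c(prof, list(rho = rho, parts = parts)))
  }
  grid <- seq(-0.9, 0.9, by = 0.1)
  ll <- vapply(grid, function(r) .ar1_profile(r, parts)$loglik, numeric(1))
  if (all(!is.finite(ll)))
    abort_ncd("AR(1) profile likelihood not finite on the rho grid",
              "ncd_convergence_error")
  r0 <- grid[which.max(ll)]
  lo <- max(r0 - 0.12, -rho_bound); hi <- min(r0 + 0.12, rho_bound)
  opt <- optimize(function(r) .ar1_profile(r, parts)$loglik,
                  interval = c(lo, hi), maximum = TRUE, tol = 1e-8)
  rho_hat <- opt$maximum
  # the boundary of the refinement window should not bind
  if (rho_hat <= lo + 1e-6 && lo > -rho_bound + 1e-9)
    rho_hat <- optimize(function(r) .ar1_profile(r, parts)$loglik,
                        interval = c(-rho_bound, hi), maximum = TRUE,
                        tol = 1e-8)$maximum
  if (rho_hat >= hi - 1e-6 && hi < rho_bound - 1e-9)
    rho_hat <- optimize(function(r) .ar1_profile(r, parts)$loglik,
                        interval = c(lo, rho_bound), maximum = TRUE,
                        tol = 1e-8)$maximum
  prof <- .ar1_profile(rho_hat, parts)
  c(prof, list(rho = rho_hat, parts = parts))
}

# R^2 of the fitted mean against the observations (not AR-whitened).
.r2 <- function(y, fitted) {
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  if (sst < 1e-12) return(if (sse < 1e-12) 1 else 0)
  1 - sse / sst
}

# Assemble a segtrend object from an ML result.
.make_segtrend <- function(series, changepoints, ml, X, call,
                           rho_fixed = FALSE, search = NULL) {
  y <- series$rate
  n <- length(y)
  p <- ncol(X)
  k <- p + 2L  # beta, rho, sigma2
  fitted <- drop(X %*% ml$beta)
  s2 <- ml$rss / max(n - p, 1L)
  vc <- s2 * solve(ml$XtX)
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(list(
    call = call,
    series = series,
    years = series$years,
    y = y,
    changepoints = as.integer(changepoints),
    coefficients = setNames(ml$beta, colnames(X)),
    rho = ml$rho,
    rho_fixed = rho_fixed,
    sigma2 = ml$sigma2,
    s2 = s2,
    vcov = vc,
    loglik = ml$loglik,
    npar = k,
    aic = 2 * k - 2 * ml$loglik,
    r2 = .r2(y, fitted),
    fitted.values = fitted,
    residuals = y - fitted,
    design = X,
    nobs = n,
    search = search
  ), class = "segtrend")
}

#' Fit a piecewise linear trend with AR(1) errors at fixed change points
#'
#' Exact Gaussian maximum likelihood for `y = X beta + e` with stationary
#' AR(1) errors, on the segmented design implied by the given change-point
#' years. `beta` and the innovation variance are profiled out in closed form;
#' the autocorrelation `rho` is maximized numerically on (-1, 1) unless fixed.
#'
#' @param series A [mortality_series()].
#' @param changepoints Change-point calendar years (0 to 3).
#' @param rho Optional fixed AR(1) coefficient (e.g. `0` for independent
#'   errors); if `NULL` (default) it is estimated.
#' @param min_gap,edge_margin Constraints checked on `changepoints`; see
#'   [validate_changepoints()].
#' @return An object of class `segtrend`; see [segtrend()] for its methods.
#' @export
fit_ar1_gls <- function(series, changepoints = integer(0), rho = NULL,
                        min_gap = 3, edge_margin = 3) {
  stopifnot(inherits(series, "mortality_series"))
  validate_series(series)
  cps <- validate_changepoints(series$years, changepoints, min_gap,
                               edge_margin)
  p <- 2L + 2L * length(cps)
  if (length(series$years) < p + 2L)
    abort_ncd(sprintf(
      "series too short (n = %d) for %d change point(s); need n >= %d",
      length(series$years), length(cps), p + 2L), "ncd_size_error")
  X <- build_segmented_design(series$years, cps)
  ml <- .ar1_ml(series$rate, X, rho = rho)
  .make_segtrend(series, cps, ml, X, match.call(),
                 rho_fixed = !is.null(rho))
}

# Order candidate indices by (AIC, number of change points, first change
# point), treating AICs within tie_eps as equal. Returns the selected index.
.select_best <- function(aics, cps_list, tie_eps = 1e-9) {
  best_aic <- min(aics)
  tied <- which(aics <= best_aic + tie_eps)
  ncp <- vapply(cps_list[tied], length, integer(1))
  tied <- tied[ncp == min(ncp)]
  if (length(tied) > 1L) {
    first <- vapply(cps_list[tied], function(s)
      if (length(s)) s[1L] else -Inf, numeric(1))
    tied <- tied[order(first)]
  }
  tied[1L]
}

# Fit every candidate change-point set and record the trace.
.search_stage <- function(series, sets, stage) {
  y <- series$rate
  res <- lapply(sets, function(cps) {
    X <- build_segmented_design(series$years, cps)
    ml <- .ar1_ml(y, X)
    k <- ncol(X) + 2L
    list(ml = ml, X = X, aic = 2 * k - 2 * ml$loglik,
         r2 = .r2(y, drop(X %*% ml$beta)))
  })
  data.frame(
    stage = stage,
    n_changepoints = vapply(sets, length, integer(1)),
    changepoints = vapply(sets, paste, character(1), collapse = "+"),
    loglik = vapply(res, function(r) r$ml$loglik, numeric(1)),
    aic = vapply(res, `[[`, numeric(1), "aic"),
    r2 = vapply(res, `[[`, numeric(1), "r2"),
    stringsAsFactors = FALSE
  ) -> trace
  list(trace = trace, res = res)
}

#' Search change points by exhaustive enumeration and AIC
#'
#' Enumerates every admissible change-point set with `0..max_cp` points
#' (pairwise at least `min_gap` years apart, each leaving `edge_margin`
#' observations on both sides), fits each by exact AR(1) maximum likelihood,
#' and returns the minimum-AIC fit. If that fit's multiple R-squared does not
#' exceed `r2_floor`, the enumeration is escalated to exactly `escalate_to`
#' change points and the better of the two stages by AIC is returned. AIC
#' ties within `tie_eps` are broken by fewer change points, then by the
#' earlier first change point.
#'
#' @inheritParams fit_ar1_gls
#' @param max_cp Maximum change points in the first-stage search.
#' @param r2_floor Escalate when the selected model's R-squared is at or
#'   below this value.
#' @param escalate_to Number of change points in the escalation stage.
#' @param tie_eps AIC tie tolerance.
#' @return A `segtrend` fit carrying the full search trace in `$search`
#'   (a data frame of every candidate's change points, log-likelihood, AIC
#'   and R-squared, plus attributes `candidate_count` and `escalated`).
#' @export
search_changepoints <- function(series, max_cp = 2, min_gap = 3,
                                edge_margin = 3, r2_floor = 0.8,
                                escalate_to = 3, tie_eps = 1e-9) {
  stopifnot(inherits(series, "mortality_series"))
  validate_series(series)
  sets <- enumerate_changepoint_sets(series$years, max_cp = max_cp,
                                     min_gap = min_gap,
                                     edge_margin = edge_margin)
  st1 <- .search_stage(series, sets, stage = 1L)
  sel <- .select_best(st1$trace$aic, sets, tie_eps)
  trace <- st1$trace
  all_sets <- sets
  all_res <- st1$res
  escalated <- FALSE
  if (st1$trace$r2[sel] <= r2_floor && escalate_to > max_cp) {
    sets2 <- tryCatch(
      enumerate_changepoint_sets(series$years, min_gap = min_gap,
                                 edge_margin = edge_margin,
                                 exact_k = escalate_to),
      ncd_config_error = function(e) NULL)
    if (!is.null(sets2)) {
      escalated <- TRUE
      st2 <- .search_stage(series, sets2, stage = 2L)
      trace <- rbind(trace, st2$trace)
      all_sets <- c(all_sets, sets2)
      all_res <- c(all_res, st2$res)
      sel <- .select_best(trace$aic, all_sets, tie_eps)
    }
  }
  attr(trace, "candidate_count") <- nrow(trace)
  attr(trace, "escalated") <- escalated
  attr(trace, "selected") <- sel
  best <- all_res[[sel]]
  fit <- .make_segtrend(series, all_sets[[sel]], best$ml, best$X,
                        match.call(), search = trace)
  fit
}

#' Piecewise linear mortality trend with AR(1) errors
#'
#' The main fitting function. Fits the annual crude mortality rate as a
#' piecewise linear function of calendar year, allowing both a level and a
#' slope change at each change point, with stationary AR(1) Gaussian errors
#' estimated by exact maximum likelihood. When `changepoints` is `NULL` the
#' change-point years are selected by exhaustive enumeration and AIC
#' minimization (see [search_changepoints()]); otherwise the given years are
#' used as-is.
#'
#' @param x A `mortality_series`, or a formula such as `rate ~ year`.
#' @param ... Passed on to [search_changepoints()] or [fit_ar1_gls()].
#' @return An object of class `segtrend` with methods `print`, `summary`,
#'   `coef`, `fitted`, `residuals`, `logLik`, `AIC`, `vcov`, `predict`,
#'   `simulate` and `plot`, plus [summarize_periods()] for period summaries.
#' @export
#' @examples
#' sc <- trend_scenario(changepoints = 2005, intercept = 700, slope = 8,
#'                      level_steps = -30, slope_deltas = -20, sigma = 5,
#'                      rho = 0.3, seed = 42)
#' s <- simulate_rate_series(sc)
#' fit <- segtrend(s)
#' fit
#' summarize_periods(fit)
segtrend <- function(x, ...) UseMethod("segtrend")

#' @rdname segtrend
#' @param changepoints Optional fixed change-point years; if `NULL`, searched.
#' @export
segtrend.mortality_series <- function(x, changepoints = NULL, ...) {
  if (is.null(changepoints)) search_changepoints(x, ...)
  else fit_ar1_gls(x, changepoints = changepoints, ...)
}

#' @rdname segtrend
#' @param data A data frame holding the formula variables (rate on the left,
#'   year on the right), e.g. from `as.data.frame(series)`.
#' @export
segtrend.formula <- function(x, data, ...) {
  mf <- model.frame(x, data)
  if (ncol(mf) != 2L)
    abort_ncd("formula must be of the form rate ~ year", "ncd_config_error")
  ser <- mortality_series(
    location = if (!is.null(data$location)) data$location[1L] else "series",
    sex = if (!is.null(data$sex)) data$sex[1L] else "both",
    cause = if (!is.null(data$cause)) data$cause[1L] else "all_four",
    years = mf[[2L]], rate = mf[[1L]])
  segtrend.mortality_series(ser, ...)
}

#' @export
print.segtrend <- function(x, ...) {
  cat("Segmented trend with AR(1) errors\n")
  cat(sprintf("  series: %s, %d-%d (n = %d)\n", series_id(x$series),
              min(x$years), max(x$years), x$nobs))
  cps <- if (length(x$changepoints)) paste(x$changepoints, collapse = ", ")
         else "none"
  cat(sprintf("  change points: %s\n", cps))
  cat(sprintf("  rho = %.3f, sigma = %.2f, AIC = %.2f, R2 = %.3f\n",
              x$rho, sqrt(x$sigma2), x$aic, x$r2))
  invisible(x)
}

#' @export
coef.segtrend <- function(object, ...) object$coefficients

#' @export
fitted.segtrend <- function(object, ...) object$fitted.values

#' @export
residuals.segtrend <- function(object,
                               type = c("response", "innovation"), ...) {
  type <- match.arg(type)
  e <- object$residuals
  if (type == "response") return(e)
  n <- length(e)
  c(e[1L] * sqrt(1 - object$rho^2), e[-1L] - object$rho * e[-n])
}

#' @export
logLik.segtrend <- function(object, ...) {
  structure(object$loglik, df = object$npar, nobs = object$nobs,
            class = "logLik")
}

#' @export
nobs.segtrend <- function(object, ...) object$nobs

#' @export
vcov.segtrend <- function(object, ...) object$vcov

#' @export
summary.segtrend <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  ct <- cbind(Estimate = object$coefficients, `Std. Error` = se,
              `t value` = object$coefficients / se)
  out <- list(call = object$call, series = series_id(object$series),
              changepoints = object$changepoints, coefficients = ct,
              rho = object$rho, sigma = sqrt(object$sigma2),
              loglik = object$loglik, aic = object$aic, r2 = object$r2,
              periods = summarize_periods(object),
              candidate_count = if (!is.null(object$search))
                attr(object$search, "candidate_count") else NA_integer_,
              escalated = if (!is.null(object$search))
                attr(object$search, "escalated") else NA)
  class(out) <- "summary.segtrend"
  out
}

#' @export
print.summary.segtrend <- function(x, digits = 4, ...) {
  cat("Segmented trend with AR(1) errors --", x$series, "\n\n")
  cat("Change points:",
      if (length(x$changepoints)) paste(x$changepoints, collapse = ", ")
      else "none", "\n")
  if (!is.na(x$candidate_count))
    cat(sprintf("Selected by AIC over %d candidate model(s)%s\n",
                x$candidate_count,
                if (isTRUE(x$escalated)) " (escalated to 3 change points)"
                else ""))
  cat("\nCoefficients:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("\nrho = %.3f, sigma = %.3f, logLik = %.3f, AIC = %.3f, R2 = %.4f\n",
              x$rho, x$sigma, x$loglik, x$aic, x$r2))
  cat("\nPeriods:\n")
  print(x$periods, row.names = FALSE)
  invisible(x)
}

#' Simulate rate series from a fitted segmented trend
#'
#' Draws new series from the fitted model: the fitted piecewise linear mean
#' plus stationary AR(1) noise with the estimated `rho` and innovation
#' variance.
#'
#' @param object A `segtrend` fit.
#' @param nsim Number of series to simulate.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @param ... Unused.
#' @return A data frame with one column per simulated series and the years as
#'   row names.
#' @export
simulate.segtrend <- function(object, nsim = 1, seed = NULL, ...) {
  n <- object$nobs
  sims <- with_seed(seed, {
    vapply(seq_len(nsim), function(j) {
      object$fitted.values + .ar1_noise(n, object$rho, sqrt(object$sigma2))
    }, numeric(n))
  })
  out <- as.data.frame(sims)
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- object$years
  out
}

# Stationary AR(1) noise path with innovation sd sigma.
.ar1_noise <- function(n, rho, sigma) {
  e <- numeric(n)
  innov <- rnorm(n)
  e[1L] <- innov[1L] * sigma / sqrt(1 - rho^2)
  for (t in seq_len(n - 1L) + 1L) e[t] <- rho * e[t - 1L] + sigma * innov[t]
  e
}
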