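# Global NCD target levels and the four-category likelihood-of-achievement
# classification, plus the short-window sensitivity analysis.

#' Global NCD target definitions
#'
#' `"who_25x25"`: a 25% relative reduction of the premature NCD mortality
#' rate by 2025 compared with the 2010 level. `"sdg_3_4_1"`: a one-third
#' relative reduction by 2030 compared with the 2015 level.
#'
#' @param name `"who_25x25"` or `"sdg_3_4_1"`.
#' @return A `target_spec` list with `name`, `baseline_year`, `reduction`
#'   and `horizon_year`.
#' @export
#' @examples
#' target_spec("who_25x25")
target_spec <- function(name = c("who_25x25", "sdg_3_4_1")) {
  name <- match.arg(name)
  out <- switch(name,
    who_25x25 = list(name = name, baseline_year = 2010L, reduction = 0.25,
                     horizon_year = 2025L),
    sdg_3_4_1 = list(name = name, baseline_year = 2015L, reduction = 1 / 3,
                     horizon_year = 2030L))
  structure(out, class = "target_spec")
}

#' @export
print.target_spec <- function(x, ...) {
  cat(sprintf("NCD target %s: %.1f%% reduction by %d vs %d level\n",
              x$name, 100 * x$reduction, x$horizon_year, x$baseline_year))
  invisible(x)
}

#' Target rate level implied by a series and a target definition
#'
#' `(1 - reduction) * rate(baseline_year)`, with the baseline rate taken
#' from the observed series (default) or from a fitted trend evaluated at the
#' baseline year.
#'
#' @param series A `mortality_series` covering the baseline year.
#' @param spec A [target_spec()].
#' @param baseline `"observed"` or `"fitted"`.
#' @param fit A `segtrend` fit, required when `baseline = "fitted"`.
#' @return The target rate level per 100,000.
#' @export
target_level <- function(series, spec, baseline = c("observed", "fitted"),
                         fit = NULL) {
  baseline <- match.arg(baseline)
  stopifnot(inherits(spec, "target_spec"))
  i <- match(spec$baseline_year, series$years)
  if (is.na(i))
    abort_ncd(sprintf("baseline year %d not in the observed series",
                      spec$baseline_year), "ncd_domain_error")
  base <- if (baseline == "observed") series$rate[i]
  else {
    if (is.null(fit))
      abort_ncd("baseline = \"fitted\" requires a fit", "ncd_config_error")
    drop(.design_at(fit, spec$baseline_year) %*% fit$coefficients)
  }
  (1 - spec$reduction) * base
}

#' Classification rule parameters
#'
#' @param likely_ci_fraction Fraction of the interval width that must lie
#'   below the target for the "Likely" category (default 0.75).
#' @param lesslikely_excess_fraction Maximum relative excess of the point
#'   prediction over the target for "Less likely" (default 0.25).
#' @return A `classification_rule` list.
#' @export
classification_rule <- function(likely_ci_fraction = 0.75,
                                lesslikely_excess_fraction = 0.25) {
  stopifnot(likely_ci_fraction > 0, likely_ci_fraction < 1,
            lesslikely_excess_fraction > 0, lesslikely_excess_fraction < 1)
  structure(list(likely_ci_fraction = likely_ci_fraction,
                 lesslikely_excess_fraction = lesslikely_excess_fraction),
            class = "classification_rule")
}

#' Fraction of an interval's width lying below a target
#'
#' `clamp((target - lo) / (hi - lo), 0, 1)`; a degenerate interval
#' (`hi == lo`) counts as entirely below the target when it is, else
#' entirely above.
#'
#' @param lo,hi Interval bounds, `lo <= hi`.
#' @param target Target rate level.
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' ci_fraction_below(100, 200, 150)  # 0.5
ci_fraction_below <- function(lo, hi, target) {
  if (any(lo > hi))
    abort_ncd("lo must not exceed hi", "ncd_domain_error")
  ifelse(hi == lo, as.numeric(hi < target),
         pmin(pmax((target - lo) / (hi - lo), 0), 1))
}

#' Four-category likelihood of achieving a target
#'
#' Categories are assigned in fixed precedence order:
#' \enumerate{
#'   \item \strong{Highly unlikely} -- the interval rules out achieving the
#'     target: `target < lo` (the whole interval is above the target level).
#'   \item \strong{Likely} -- the point prediction is below the target and
#'     more than 75% of the interval's width lies below it.
#'   \item \strong{Less likely} -- the point prediction is no more than 25%
#'     above the target.
#'   \item \strong{Unlikely} -- otherwise.
#' }
#' The rule is a total, deterministic function of
#' `(point, lo, hi, target)` and is invariant to rescaling all four by any
#' positive constant.
#'
#' @param point Point prediction.
#' @param lo,hi 95% interval bounds with `lo <= point <= hi`.
#' @param target Positive target rate level.
#' @param rule A [classification_rule()].
#' @return One of `"Likely"`, `"Less likely"`, `"Unlikely"`,
#'   `"Highly unlikely"` (vectorized over the inputs).
#' @export
#' @examples
#' classify_likelihood(360.6, 260.1, 461.1, 494.3)  # "Likely"
#' classify_likelihood(537.6, 486.2, 589.0, 357.7)  # "Highly unlikely"
classify_likelihood <- function(point, lo, hi, target,
                                rule = classification_rule()) {
  if (any(target <= 0))
    abort_ncd("target must be positive", "ncd_domain_error")
  if (any(lo > hi))
    abort_ncd("lo must not exceed hi", "ncd_domain_error")
  n <- max(length(point), length(lo), length(hi), length(target))
  point <- rep_len(point, n); lo <- rep_len(lo, n)
  hi <- rep_len(hi, n); target <- rep_len(target, n)
  frac <- ci_fraction_below(lo, hi, target)
  ifelse(target < lo, "Highly unlikely",
    ifelse(point < target & frac > rule$likely_ci_fraction, "Likely",
      ifelse(point <= (1 + rule$lesslikely_excess_fraction) * target,
             "Less likely", "Unlikely")))
}

#' Short-window sensitivity analysis
#'
#' Refits the rate series with a simple linear regression (no change points,
#' independent errors) restricted to the window from the target's baseline
#' year to the end of the series (2010-2019 for the 2025 target, 2015-2019
#' for the 2030 target when data end in 2019), forecasts the horizon year
#' with the standard 95% least-squares prediction interval, and classifies
#' achievement with the same rule.
#'
#' @param series A `mortality_series` fully covering the window.
#' @param spec A [target_spec()].
#' @param rule A [classification_rule()].
#' @param level Interval coverage.
#' @return One-row data frame with `id`, `target_name`, `horizon_year`,
#'   `point`, `lo`, `hi`, `target_level`, `category` and
#'   `method = "simple_linear"`.
#' @export
sensitivity_forecast <- function(series, spec, rule = classification_rule(),
                                 level = 0.95) {
  stopifnot(inherits(series, "mortality_series"),
            inherits(spec, "target_spec"))
  last <- max(series$years)
  window <- spec$baseline_year:last
  if (!all(window %in% series$years))
    abort_ncd(sprintf("window %d-%d not fully observed",
                      spec$baseline_year, last), "ncd_gap_error")
  if (length(window) < 4L)
    abort_ncd("sensitivity window has fewer than 4 points", "ncd_size_error")
  idx <- match(window, series$years)
  dat <- data.frame(year = window, rate = series$rate[idx])
  lmfit <- lm(rate ~ year, data = dat)
  pr <- predict(lmfit, newdata = data.frame(year = spec$horizon_year),
                interval = "prediction", level = level)
  tgt <- target_level(series, spec)
  data.frame(id = series_id(series), target_name = spec$name,
             horizon_year = spec$horizon_year,
             point = pr[1L, "fit"], lo = pr[1L, "lwr"], hi = pr[1L, "upr"],
             target_level = tgt,
             category = classify_likelihood(pr[1L, "fit"], pr[1L, "lwr"],
                                            pr[1L, "upr"], tgt, rule),
             method = "simple_linear", stringsAsFactors = FALSE)
}

#' Assess all series against both global NCD targets
#'
#' For each fitted trend and each target definition: forecast the horizon
#' year with the simulation interval, compute the target level from the
#' series, and classify. Deterministic given `seed` (each (fit, target) pair
#' uses a seed derived from it).
#'
#' @param fits A named list of `segtrend` fits (or a single fit).
#' @param specs List of [target_spec()]s; defaults to both global targets.
#' @param rule A [classification_rule()].
#' @param baseline Baseline mode passed to [target_level()].
#' @param nsim,seed Simulation settings for the forecast intervals.
#' @param interval Interval type; see [predict.segtrend()].
#' @return Data frame with one row per (series, target): `id`,
#'   `target_name`, `horizon_year`, `point`, `lo`, `hi`, `target_level`,
#'   `category`, `method`.
#' @export
assess_all <- function(fits, specs = list(target_spec("who_25x25"),
                                          target_spec("sdg_3_4_1")),
                       rule = classification_rule(),
                       baseline = "observed", nsim = 10000, seed = 1,
                       interval = "mean") {
  if (inherits(fits, "segtrend")) fits <- list(fits)
  if (!length(fits)) {
    return(data.frame(id = character(0), target_name = character(0),
                      horizon_year = integer(0), point = numeric(0),
                      lo = numeric(0), hi = numeric(0),
                      target_level = numeric(0), category = character(0),
                      method = character(0), stringsAsFactors = FALSE))
  }
  seeds <- derive_seeds(seed, length(fits) * length(specs))
  rows <- list()
  k <- 0L
  for (i in seq_along(fits)) {
    fit <- fits[[i]]
    for (j in seq_along(specs)) {
      k <- k + 1L
      spec <- specs[[j]]
      fc <- forecast_rate(fit, spec$horizon_year, nsim = nsim,
                          seed = seeds[k], interval = interval)
      tgt <- target_level(fit$series, spec, baseline = baseline, fit = fit)
      rows[[k]] <- data.frame(
        id = series_id(fit$series), target_name = spec$name,
        horizon_year = spec$horizon_year, point = fc$point, lo = fc$lo,
        hi = fc$hi, target_level = tgt,
        category = classify_likelihood(fc$point, fc$lo, fc$hi, tgt, rule),
        method = fc$method, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Export assessments (or a fit) to JSON for provenance
#'
#' @param x An assessment data frame from [assess_all()], or a `segtrend`
#'   fit.
#' @param path Output JSON path.
#' @param ... Extra fields (e.g. seeds, rule parameters) stored alongside.
#' @return `path`, invisibly.
#' @export
export_json <- function(x, path, ...) {
  extra <- list(...)
  payload <- if (inherits(x, "segtrend")) {
    list(type = "segtrend_fit", series = series_id(x$series),
         years = x$years, changepoints = x$changepoints,
         coefficients = as.list(x$coefficients), rho = x$rho,
         sigma2 = x$sigma2, loglik = x$loglik, aic = x$aic, r2 = x$r2,
         fitted = x$fitted.values,
         search = if (!is.null(x$search)) as.list(x$search) else NULL)
  } else list(type = "assessments", records = x)
  jsonlite::write_json(c(payload, extra), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
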