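# Synthetic rate series and GBD-format age-stratified counts with the
# statistical structure the trend analysis assumes, so the whole pipeline is
# testable without an external download.

#' Define a synthetic trend scenario
#'
#' A scenario is a piecewise linear mean trend (0-3 change points, each with
#' a level step and a slope change) plus stationary AR(1) noise, over an
#' annual year range.
#'
#' @param first_year,last_year Year range (default 1990-2019, thirty annual
#'   observations).
#' @param changepoints Change-point calendar years (must satisfy the same
#'   gap/edge rules as the fitting search).
#' @param intercept Mean rate at `first_year`, per 100,000.
#' @param slope Initial trend slope, rate units per year.
#' @param level_steps,slope_deltas Per change point: jump in level and change
#'   in slope at that year.
#' @param rho AR(1) coefficient of the noise, in (-1, 1).
#' @param sigma Innovation standard deviation, rate units.
#' @param seed Integer seed used by [simulate_rate_series()].
#' @param name Scenario label (becomes the series' location).
#' @return A `trend_scenario` object.
#' @export
#' @examples
#' trend_scenario(changepoints = c(1996, 2005), intercept = 650, slope = 25,
#'                level_steps = c(0, -30), slope_deltas = c(-40, 5),
#'                rho = 0.3, sigma = 8, seed = 1)
trend_scenario <- function(first_year = 1990, last_year = 2019,
                           changepoints = integer(0), intercept = 600,
                           slope = 0, level_steps = numeric(0),
                           slope_deltas = numeric(0), rho = 0, sigma = 0,
                           seed = 1, name = "synthetic") {
  years <- seq(as.integer(first_year), as.integer(last_year))
  cps <- validate_changepoints(years, changepoints)
  if (length(level_steps) != length(cps) ||
      length(slope_deltas) != length(cps))
    abort_ncd("level_steps and slope_deltas must match changepoints in length",
              "ncd_scenario_error")
  if (abs(rho) >= 1)
    abort_ncd("rho must lie in (-1, 1)", "ncd_scenario_error")
  if (sigma < 0)
    abort_ncd("sigma must be non-negative", "ncd_scenario_error")
  sc <- structure(list(first_year = years[1L], last_year = years[length(years)],
                       years = years, changepoints = cps,
                       intercept = intercept, slope = slope,
                       level_steps = level_steps, slope_deltas = slope_deltas,
                       rho = rho, sigma = sigma, seed = as.integer(seed),
                       name = name),
                  class = "trend_scenario")
  if (any(scenario_mean(sc) < 0))
    abort_ncd("scenario implies negative mean rates", "ncd_scenario_error")
  sc
}

#' @export
print.trend_scenario <- function(x, ...) {
  cat(sprintf("Trend scenario '%s': %d-%d\n", x$name, x$first_year,
              x$last_year))
  cat(sprintf("  changepoints: %s; rho = %.2f, sigma = %.1f, seed = %d\n",
              if (length(x$changepoints)) paste(x$changepoints, collapse = ", ")
              else "none", x$rho, x$sigma, x$seed))
  invisible(x)
}

#' Noiseless mean trend of a scenario
#'
#' The piecewise linear mean, exactly representable in the column space of
#' [build_segmented_design()] (the truth lies in the fitted model class).
#'
#' @param scenario A `trend_scenario`.
#' @return Numeric vector of mean rates, one per year.
#' @export
scenario_mean <- function(scenario) {
  X <- build_segmented_design(scenario$years, scenario$changepoints)
  beta <- c(scenario$intercept, scenario$slope,
            rbind(scenario$level_steps, scenario$slope_deltas))
  drop(X %*% beta)
}

#' Simulate an annual rate series from a scenario
#'
#' `rate_t = mean_trend(t) + e_t` with `e_t` a stationary AR(1) path
#' (`e_1` drawn from the stationary distribution) with innovation sd
#' `sigma`. The same seed always yields the identical series. The noiseless
#' truth and generating scenario are attached as attribute `"truth"`.
#'
#' @param scenario A [trend_scenario()].
#' @return A `mortality_series` (sex `"both"`, cause `"all_four"`, location
#'   the scenario name) with attribute `truth = list(scenario, mean)`.
#' @export
simulate_rate_series <- function(scenario) {
  stopifnot(inherits(scenario, "trend_scenario"))
  mu <- scenario_mean(scenario)
  n <- length(scenario$years)
  noise <- with_seed(scenario$seed,
                     .ar1_noise(n, scenario$rho, scenario$sigma))
  ser <- mortality_series(scenario$name, "both", "all_four",
                          scenario$years, mu + noise)
  attr(ser, "truth") <- list(scenario = scenario, mean = mu)
  ser
}

#' Age pattern for distributing deaths across 5-year bands
#'
#' Band-level shares of total deaths (summing to 1) and band populations.
#' Defaults emulate the steep age gradient of NCD mortality between ages 30
#' and 69 and a population pyramid thinning with age.
#'
#' @param shares Eight non-negative death shares summing to 1 (bands 30-34
#'   through 65-69).
#' @param populations Eight positive band populations.
#' @return An `age_pattern` object.
#' @export
age_pattern <- function(shares = c(0.02, 0.03, 0.05, 0.08, 0.12, 0.17,
                                   0.24, 0.29),
                        populations = c(760, 730, 690, 650, 600, 545, 490,
                                        435) * 1000) {
  if (length(shares) != 8L || length(populations) != 8L)
    abort_ncd("shares and populations must have length 8", "ncd_domain_error")
  if (any(shares < 0) || abs(sum(shares) - 1) > 1e-12)
    abort_ncd("shares must be non-negative and sum to 1", "ncd_domain_error")
  if (any(populations <= 0))
    abort_ncd("populations must be positive", "ncd_domain_error")
  structure(list(shares = shares, populations = populations,
                 bands = AGE_BANDS), class = "age_pattern")
}

#' Age-stratified counts consistent with a rate series
#'
#' Converts each year's rate into a total death count over the pattern's
#' total population, rounds it to an integer, and apportions it across the
#' eight age bands by largest-remainder so band deaths are integers summing
#' exactly to the rounded total. The crude rate recomputed from the counts
#' therefore differs from the input rate by less than one death's worth
#' (`1e5 / total_population`). Optionally writes a GBD-Results-dialect CSV.
#'
#' @param series A `mortality_series` with non-negative rates.
#' @param pattern An [age_pattern()].
#' @param path Optional path to write a GBD-dialect CSV (columns `measure`,
#'   `location`, `sex`, `age`, `cause`, `metric`, `year`, `val`).
#' @param seed Accepted for interface stability; unused (the apportionment
#'   is deterministic).
#' @return An [age_counts()] object.
#' @export
simulate_age_counts <- function(series, pattern = age_pattern(), path = NULL,
                                seed = NULL) {
  stopifnot(inherits(series, "mortality_series"))
  if (any(series$rate < 0))
    abort_ncd("rates must be non-negative", "ncd_domain_error")
  pop_total <- sum(pattern$populations)
  recs <- lapply(seq_along(series$years), function(i) {
    total <- round(series$rate[i] * pop_total / 1e5)
    quota <- pattern$shares * total
    base <- floor(quota)
    rem <- as.integer(total - sum(base))
    if (rem > 0L) {
      extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    data.frame(year = series$years[i], age_group = pattern$bands,
               deaths = base, population = pattern$populations,
               stringsAsFactors = FALSE)
  })
  counts <- age_counts(series$location, series$sex, series$cause,
                       do.call(rbind, recs))
  if (!is.null(path)) write_gbd_csv(counts, path)
  counts
}

#' Write age-stratified counts as a GBD-Results-dialect CSV
#'
#' @param counts An [age_counts()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gbd_csv <- function(counts, path) {
  rec <- counts$records
  mk <- function(metric, value)
    data.frame(measure = ifelse(metric == "deaths", "Deaths", "Population"),
               location = counts$location, sex = counts$sex,
               age = rec$age_group, cause = counts$cause, metric = metric,
               year = rec$year, val = value, stringsAsFactors = FALSE)
  out <- rbind(mk("deaths", rec$deaths), mk("population", rec$population))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default scenario grid
#'
#' Four qualitative regimes mirroring the trend shapes seen in Eastern
#' European and Central Asian premature NCD mortality over 1990-2019:
#' rise-then-fall, fall-then-rise, monotone decline, and near-flat, at rate
#' scales between roughly 400 and 1000 per 100,000, with moderately
#' autocorrelated noise.
#'
#' @return Named list of [trend_scenario()]s.
#' @export
default_scenario_grid <- function() {
  list(
    rise_fall = trend_scenario(
      changepoints = c(1996, 2010), intercept = 650, slope = 25,
      level_steps = c(0, -20), slope_deltas = c(-40, 5),
      rho = 0.3, sigma = 8, seed = 101, name = "rise_fall"),
    fall_rise = trend_scenario(
      changepoints = 2005, intercept = 800, slope = -12,
      level_steps = -15, slope_deltas = 20,
      rho = 0.3, sigma = 8, seed = 102, name = "fall_rise"),
    decline = trend_scenario(
      intercept = 900, slope = -10, rho = 0.3, sigma = 8, seed = 103,
      name = "decline"),
    flat = trend_scenario(
      intercept = 600, slope = 0, rho = 0.3, sigma = 8, seed = 104,
      name = "flat"))
}

#' Build a parameter-recovery suite
#'
#' Deterministically expands scenario templates into `n_reps` replicates
#' each, with per-replicate seeds derived from one master seed, carrying the
#' generating truth for later scoring.
#'
#' @param n_reps Replicates per template (>= 1).
#' @param scenario_grid List of [trend_scenario()] templates.
#' @param master_seed Integer master seed.
#' @return A `recovery_suite`: list of `list(series, truth)` items.
#' @export
make_recovery_suite <- function(n_reps, scenario_grid = default_scenario_grid(),
                                master_seed = 1) {
  stopifnot(n_reps >= 1)
  seeds <- derive_seeds(master_seed, n_reps * length(scenario_grid))
  items <- list()
  k <- 0L
  for (tmpl in scenario_grid) {
    for (r in seq_len(n_reps)) {
      k <- k + 1L
      sc <- tmpl
      sc$seed <- seeds[k]
      sc$name <- sprintf("%s_rep%03d", tmpl$name, r)
      ser <- simulate_rate_series(sc)
      items[[k]] <- list(series = ser, truth = attr(ser, "truth"))
    }
  }
  structure(items, class = "recovery_suite")
}

#' Score change-point recovery over a suite
#'
#' Runs the change-point search on every item whose truth has exactly one
#' change point and reports the fraction selected within `tol_years` of the
#' true year.
#'
#' @param suite A [make_recovery_suite()] result (or any list of
#'   `list(series, truth)`).
#' @param tol_years Tolerance in years (default 1).
#' @param ... Passed to [search_changepoints()].
#' @return List with `n`, `n_hit`, `rate` (fraction in `[0, 1]`) and the
#'   per-item selected change points.
#' @export
score_changepoint_recovery <- function(suite, tol_years = 1, ...) {
  one_cp <- Filter(function(it)
    length(it$truth$scenario$changepoints) == 1L, suite)
  sel <- lapply(one_cp, function(it)
    search_changepoints(it$series, ...)$changepoints)
  hit <- mapply(function(it, s)
    length(s) >= 1L &&
      min(abs(s - it$truth$scenario$changepoints)) <= tol_years,
    one_cp, sel)
  list(n = length(one_cp), n_hit = sum(hit),
       rate = if (length(one_cp)) mean(hit) else NA_real_, selected = sel)
}
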