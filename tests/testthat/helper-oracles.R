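# Shared fixtures and independent oracles used across the test files.

BANDS <- c("30-34", "35-39", "40-44", "45-49", "50-54", "55-59", "60-64",
           "65-69")

# Write a GBD-Results-dialect CSV with given per-(year, band) deaths and
# populations. `deaths` and `pop` are matrices (years x 8 bands).
write_gbd_fixture <- function(path, years, deaths, pop,
                              location = "Testland", sex = "both",
                              cause = "all_four", age_labels = BANDS,
                              shuffle = FALSE) {
  rows <- list()
  for (i in seq_along(years)) {
    for (j in seq_along(age_labels)) {
      rows[[length(rows) + 1L]] <- data.frame(
        measure = "Deaths", location = location, sex = sex,
        age = age_labels[j], cause = cause, metric = "deaths",
        year = years[i], val = deaths[i, j], stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        measure = "Population", location = location, sex = sex,
        age = age_labels[j], cause = cause, metric = "population",
        year = years[i], val = pop[i, j], stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  if (shuffle) df <- df[sample.int(nrow(df)), ]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Closed-form least-squares oracle.
ols_oracle <- function(y, X) drop(solve(crossprod(X), crossprod(X, y)))

# Independent profile-likelihood computation at one rho (explicit
# Prais-Winsten transform and lm.fit; no shared code with the package
# internals).
profile_ll_oracle <- function(rho, yy, Xd) {
  n <- length(yy)
  ys <- c(sqrt(1 - rho^2) * yy[1L], yy[-1L] - rho * yy[-n])
  Xs <- rbind(sqrt(1 - rho^2) * Xd[1L, ], Xd[-1L, , drop = FALSE] -
                rho * Xd[-n, , drop = FALSE])
  rss <- sum(lm.fit(Xs, ys)$residuals^2)
  -0.5 * n * (log(2 * pi * rss / n) + 1) + 0.5 * log(1 - rho^2)
}

# Brute-force grid maximization of the profile likelihood.
grid_ml_oracle <- function(yy, Xd, step = 0.001, bound = 0.95) {
  grid <- seq(-bound, bound, by = step)
  max(vapply(grid, profile_ll_oracle, numeric(1), yy = yy, Xd = Xd))
}

# A 30-year one-change-point scenario used in several fitting tests.
one_cp_scenario <- function(seed = 1, rho = 0.3, sigma = 8) {
  trend_scenario(changepoints = 2005, intercept = 600, slope = 8,
                 level_steps = -50, slope_deltas = -16, rho = rho,
                 sigma = sigma, seed = seed, name = "one_cp")
}
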