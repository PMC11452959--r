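# Forecasting, target levels and the likelihood classification.

test_that("a noiseless fit forecasts the exact line with a collapsed interval", {
  s <- mortality_series("x", "both", "all_four", 1990:2019, 100 + 2 * (0:29))
  fit <- fit_ar1_gls(s)
  fc <- forecast_rate(fit, 2025, nsim = 1000, seed = 5)
  expect_equal(fc$point, 170, tolerance = 1e-8)
  expect_equal(fc$lo, 170, tolerance = 1e-6)
  expect_equal(fc$hi, 170, tolerance = 1e-6)
})

test_that("interval width is non-decreasing in the horizon", {
  s <- simulate_rate_series(one_cp_scenario(seed = 71))
  fit <- fit_ar1_gls(s, 2005)
  pr <- predict(fit, years = c(2025, 2030), interval = "mean",
                nsim = 8000, seed = 9)
  expect_lte(pr$upr[1] - pr$lwr[1], pr$upr[2] - pr$lwr[2])
  # the point prediction is the final-segment line extrapolated
  b <- coef(fit)
  line_2025 <- b[1] + b[2] * 35 + b[3] + b[4] * 20
  expect_equal(pr$fit[1], unname(line_2025))
  # prediction intervals are at least as wide as trend intervals
  pp <- predict(fit, years = c(2025, 2030), interval = "prediction",
                nsim = 8000, seed = 9)
  expect_gte(pp$upr[1] - pp$lwr[1], pr$upr[1] - pr$lwr[1])
  # identical seeds reproduce identical intervals
  pr2 <- predict(fit, years = c(2025, 2030), interval = "mean",
                 nsim = 8000, seed = 9)
  expect_identical(pr, pr2)
})

test_that("forecasting before the data end is rejected", {
  s <- simulate_rate_series(one_cp_scenario(seed = 72))
  fit <- fit_ar1_gls(s, 2005)
  expect_error(forecast_rate(fit, 2019), class = "ncd_domain_error")
})

test_that("target specs and levels follow the global target definitions", {
  who <- target_spec("who_25x25")
  sdg <- target_spec("sdg_3_4_1")
  expect_equal(who$baseline_year, 2010L)
  expect_equal(who$reduction, 0.25)
  expect_equal(who$horizon_year, 2025L)
  expect_equal(sdg$baseline_year, 2015L)
  expect_equal(sdg$reduction, 1 / 3)
  expect_equal(sdg$horizon_year, 2030L)

  rate <- rep(600, 30)
  s <- mortality_series("x", "both", "all_four", 1990:2019, rate)
  expect_equal(target_level(s, who), 450)
  expect_equal(target_level(s, sdg), 400)
  # inversion: a 2025 target of 494.3 implies a 2010 baseline of 494.3/0.75
  s2 <- mortality_series("x", "both", "all_four", 1990:2019,
                         rep(494.3 / 0.75, 30))
  expect_equal(target_level(s2, who), 494.3, tolerance = 1e-9)
  # linear in the baseline rate
  s3 <- mortality_series("x", "both", "all_four", 1990:2019, 3 * rate)
  expect_equal(target_level(s3, who), 3 * target_level(s, who))
  short <- mortality_series("x", "both", "all_four", 1990:2005, rep(600, 16))
  expect_error(target_level(short, sdg), class = "ncd_domain_error")
})

test_that("ci_fraction_below measures the interval width below the target", {
  expect_equal(ci_fraction_below(260.1, 461.1, 494.3), 1)
  expect_equal(ci_fraction_below(486.2, 589.0, 357.7), 0)
  expect_equal(ci_fraction_below(100, 200, 150), 0.5)
  expect_equal(ci_fraction_below(100, 100, 150), 1)  # degenerate, below
  expect_equal(ci_fraction_below(200, 200, 150), 0)  # degenerate, above
})

test_that("classification reproduces published example cells", {
  expect_equal(classify_likelihood(360.6, 260.1, 461.1, 494.3), "Likely")
  expect_equal(classify_likelihood(537.6, 486.2, 589.0, 357.7),
               "Highly unlikely")
  expect_equal(classify_likelihood(353.6, 306.1, 401.1, 337.3),
               "Less likely")
})

test_that("classification is total, scale-invariant and monotone in the point", {
  set.seed(73)
  cats <- c("Likely", "Less likely", "Unlikely", "Highly unlikely")
  for (i in 1:200) {
    lo <- runif(1, 50, 900)
    hi <- lo + runif(1, 0, 400)
    point <- runif(1, lo, hi)
    target <- runif(1, 10, 1200)
    got <- classify_likelihood(point, lo, hi, target)
    expect_true(got %in% cats)
    cc <- runif(1, 0.1, 10)
    expect_identical(
      classify_likelihood(cc * point, cc * lo, cc * hi, cc * target), got)
    # decreasing the point never worsens the category; "Highly unlikely"
    # is interval-determined, so the point cannot move a series out of it
    if (got != "Highly unlikely") {
      rank3 <- c(Likely = 1, "Less likely" = 2, Unlikely = 3)
      lower <- classify_likelihood(max(point - runif(1, 0, point / 2), lo),
                                   lo, hi, target)
      expect_lte(rank3[[lower]], rank3[[got]])
    }
  }
})

test_that("sensitivity analysis fits the short window with an OLS oracle", {
  # exactly linear decline reaching 0.70 x baseline at the horizon
  base <- 800
  years <- 1990:2019
  slope <- (0.70 * base - base) / (2025 - 2010)
  rate <- base + slope * (years - 2010)
  s <- mortality_series("x", "both", "all_four", years, rate)
  a <- sensitivity_forecast(s, target_spec("who_25x25"))
  expect_equal(a$point, 0.70 * base, tolerance = 1e-8)
  expect_equal(a$category, "Likely")

  # constant at baseline: point prediction equals baseline, above target
  s2 <- mortality_series("x", "both", "all_four", years, rep(base, 30))
  a2 <- sensitivity_forecast(s2, target_spec("who_25x25"))
  expect_false(a2$category == "Likely")

  # closed-form least-squares oracle on a noisy 10-point window
  set.seed(74)
  rate3 <- 700 - 6 * (years - 1990) + rnorm(30, sd = 8)
  s3 <- mortality_series("x", "both", "all_four", years, rate3)
  a3 <- sensitivity_forecast(s3, target_spec("who_25x25"))
  w <- years >= 2010
  X <- cbind(1, years[w])
  y <- rate3[w]
  bhat <- solve(crossprod(X), crossprod(X, y))
  res <- y - X %*% bhat
  s2hat <- sum(res^2) / (sum(w) - 2)
  xh <- c(1, 2025)
  pt <- drop(xh %*% bhat)
  se_pred <- sqrt(s2hat * (1 + drop(t(xh) %*% solve(crossprod(X)) %*% xh)))
  tq <- qt(0.975, sum(w) - 2)
  expect_equal(a3$point, pt, tolerance = 1e-9)
  expect_equal(a3$lo, pt - tq * se_pred, tolerance = 1e-9)
  expect_equal(a3$hi, pt + tq * se_pred, tolerance = 1e-9)
})

test_that("sensitivity and segmented forecasts agree on a clean linear series", {
  sc <- trend_scenario(intercept = 700, slope = -6, rho = 0, sigma = 2,
                       seed = 75)
  s <- simulate_rate_series(sc)
  fit <- fit_ar1_gls(s)  # zero change points
  fc <- forecast_rate(fit, 2025, nsim = 4000, seed = 76)
  sa <- sensitivity_forecast(s, target_spec("who_25x25"))
  expect_equal(fc$point, sa$point, tolerance = 5)
})

test_that("assess_all produces one deterministic row per series and target", {
  fits <- list(
    a = fit_ar1_gls(simulate_rate_series(one_cp_scenario(seed = 77)), 2005),
    b = fit_ar1_gls(simulate_rate_series(
      trend_scenario(intercept = 700, slope = -6, rho = 0.3, sigma = 8,
                     seed = 78, name = "b"))))
  tb <- assess_all(fits, nsim = 2000, seed = 11)
  expect_equal(nrow(tb), 4L)
  expect_setequal(tb$horizon_year, c(2025L, 2030L))
  expect_true(all(tb$lo <= tb$point & tb$point <= tb$hi))
  tb2 <- assess_all(fits, nsim = 2000, seed = 11)
  expect_identical(tb, tb2)
  empty <- assess_all(list())
  expect_equal(nrow(empty), 0L)
})
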