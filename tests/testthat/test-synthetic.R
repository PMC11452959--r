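# Synthetic rate series and age-stratified count generation.

test_that("sigma = 0 yields exactly the piecewise-linear mean", {
  sc <- trend_scenario(changepoints = 2000, intercept = 600, slope = 5,
                       level_steps = -40, slope_deltas = -12, sigma = 0,
                       seed = 3)
  s <- simulate_rate_series(sc)
  expect_identical(s$rate, scenario_mean(sc))
  expect_identical(s$rate, attr(s, "truth")$mean)
})

test_that("the same seed reproduces the identical series", {
  sc <- one_cp_scenario(seed = 81)
  expect_identical(simulate_rate_series(sc)$rate,
                   simulate_rate_series(sc)$rate)
  sc2 <- one_cp_scenario(seed = 82)
  expect_false(identical(simulate_rate_series(sc)$rate,
                         simulate_rate_series(sc2)$rate))
})

test_that("the noise process has the requested lag-1 autocorrelation", {
  sc <- trend_scenario(first_year = 1, last_year = 2000, intercept = 600,
                       slope = 0, rho = 0.5, sigma = 10, seed = 83)
  s <- simulate_rate_series(sc)
  noise <- s$rate - attr(s, "truth")$mean
  r1 <- acf(noise, lag.max = 1, plot = FALSE)$acf[2L]
  expect_lt(abs(r1 - 0.5), 0.05)
  expect_lt(abs(sd(noise) - 10 / sqrt(1 - 0.25)), 1)
})

test_that("scenarios implying negative mean rates are rejected", {
  expect_error(
    trend_scenario(intercept = 100, slope = -10, seed = 1),
    class = "ncd_scenario_error")
  expect_error(
    trend_scenario(changepoints = 2000, intercept = 600, slope = 5,
                   level_steps = -40, rho = 0, seed = 1),
    class = "ncd_scenario_error")  # mismatched slope_deltas length
})

test_that("age counts apportion deaths exactly and reconstruct the rate", {
  sc <- one_cp_scenario(seed = 84)
  s <- simulate_rate_series(sc)
  pat <- age_pattern()
  counts <- simulate_age_counts(s, pat)
  pop_total <- sum(pat$populations)
  rec <- counts$records
  # integer deaths summing to the rounded yearly total
  expect_true(all(rec$deaths == round(rec$deaths)))
  by_year <- tapply(rec$deaths, rec$year, sum)
  expect_equal(as.numeric(by_year),
               round(s$rate * pop_total / 1e5))
  # reconstructed rate within one death's worth
  back <- compute_premature_rate(counts)
  expect_lt(max(abs(back$rate - s$rate)), 1e5 / pop_total)
})

test_that("degenerate and symmetric share patterns behave as expected", {
  s <- mortality_series("x", "both", "all_four", 2000:2002,
                        c(400, 500, 600))
  one_band <- age_pattern(shares = c(0, 0, 0, 0, 0, 0, 0, 1))
  c1 <- simulate_age_counts(s, one_band)
  rec <- c1$records
  pop_total <- sum(one_band$populations)
  expect_equal(rec$deaths[rec$age_group == "65-69"],
               round(s$rate * pop_total / 1e5))
  expect_true(all(rec$deaths[rec$age_group != "65-69"] == 0))

  equal <- age_pattern(shares = rep(1 / 8, 8), populations = rep(5e5, 8))
  c2 <- simulate_age_counts(s, equal)
  spread <- tapply(c2$records$deaths, c2$records$year,
                   function(d) max(d) - min(d))
  expect_true(all(spread <= 1))
})

test_that("counts round-trip through the GBD CSV dialect", {
  path <- withr::local_tempfile(fileext = ".csv")
  sc <- one_cp_scenario(seed = 85)
  s <- simulate_rate_series(sc)
  simulate_age_counts(s, path = path)
  counts <- read_gbd_results(path)
  expect_length(counts, 1L)
  back <- compute_premature_rate(counts[[1L]])
  expect_lt(max(abs(back$rate - s$rate)),
            1e5 / sum(age_pattern()$populations))
})

test_that("recovery suites expand deterministically with distinct seeds", {
  grid <- default_scenario_grid()[c("fall_rise", "decline")]
  a <- make_recovery_suite(3, grid, master_seed = 42)
  b <- make_recovery_suite(3, grid, master_seed = 42)
  expect_length(a, 6L)
  seeds <- vapply(a, function(it) it$truth$scenario$seed, integer(1))
  expect_equal(length(unique(seeds)), 6L)
  expect_identical(lapply(a, function(it) it$series$rate),
                   lapply(b, function(it) it$series$rate))
  c_ <- make_recovery_suite(3, grid, master_seed = 43)
  expect_false(identical(a[[1L]]$series$rate, c_[[1L]]$series$rate))
  # each item carries scoreable truth
  expect_true(all(vapply(a, function(it)
    inherits(it$truth$scenario, "trend_scenario"), logical(1))))
})

test_that("the default grid round-trips through counts within the bound", {
  pat <- age_pattern()
  bound <- 1e5 / sum(pat$populations)
  for (sc in default_scenario_grid()) {
    s <- simulate_rate_series(sc)
    back <- compute_premature_rate(simulate_age_counts(s, pat))
    expect_lt(max(abs(back$rate - s$rate)), bound)
  }
})
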