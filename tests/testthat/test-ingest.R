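# GBD-style CSV ingestion and crude 30-69 rate construction.

test_that("a 2-year x 8-band fixture round-trips and aggregates correctly", {
  path <- withr::local_tempfile(fileext = ".csv")
  set.seed(31)
  deaths <- matrix(sample(50:500, 16), 2, 8)
  pop <- matrix(sample(4e5:8e5, 16), 2, 8)
  write_gbd_fixture(path, 2000:2001, deaths, pop)
  counts <- read_gbd_results(path)
  expect_length(counts, 1L)
  cc <- counts[[1L]]
  expect_s3_class(cc, "age_counts")
  expect_equal(nrow(cc$records), 16L)
  ser <- compute_premature_rate(cc)
  # independent sum-then-divide oracle
  expect_equal(ser$rate, 1e5 * rowSums(deaths) / rowSums(pop),
               tolerance = 1e-9)
  expect_equal(ser$years, 2000:2001)
})

test_that("deleted population rows yield an integrity error naming years", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_gbd_fixture(path, 2000:2001, matrix(100, 2, 8), matrix(5e5, 2, 8))
  df <- read.csv(path)
  write.csv(df[df$metric != "population", ], path, row.names = FALSE)
  err <- expect_error(read_gbd_results(path), class = "ncd_integrity_error")
  expect_match(conditionMessage(err), "2000")
  expect_match(conditionMessage(err), "2001")
})

test_that("age bands outside 30-69 are dropped with a warning, output unchanged", {
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  set.seed(32)
  deaths <- matrix(sample(50:500, 16), 2, 8)
  pop <- matrix(sample(4e5:8e5, 16), 2, 8)
  write_gbd_fixture(p1, 2000:2001, deaths, pop)
  # same fixture plus a 25-29 band
  df <- read.csv(p1)
  extra <- df[df$age == "30-34", ]
  extra$age <- "25-29"
  write.csv(rbind(df, extra), p2, row.names = FALSE)
  clean <- read_gbd_results(p1)
  expect_warning(noisy <- read_gbd_results(p2),
                 class = "ncd_age_range_warning")
  expect_equal(noisy[[1L]]$records, clean[[1L]]$records)
})

test_that("label dialects are normalized and schema errors are caught", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_gbd_fixture(path, 2000, matrix(100, 1, 8), matrix(5e5, 1, 8),
                    age_labels = c("30 to 34", "35 to 39", "40-44", "45-49",
                                   "50-54", "55-59", "60-64", "65 to 69"))
  counts <- read_gbd_results(path)
  expect_setequal(unique(counts[[1L]]$records$age_group), BANDS)

  df <- read.csv(path)
  names(df)[names(df) == "val"] <- "value_estimate"
  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, p2, row.names = FALSE)
  expect_error(read_gbd_results(p2), class = "ncd_schema_error")
  df$val <- "not-a-number"
  write.csv(df, p2, row.names = FALSE)
  expect_error(read_gbd_results(p2, gbd_schema()), class = "ncd_parse_error")
})

test_that("crude rate arithmetic matches hand calculations", {
  rec <- data.frame(year = 2000L, age_group = BANDS,
                    deaths = c(10, 20, 0, 0, 0, 0, 0, 0),
                    population = rep(1000, 8))
  ser <- compute_premature_rate(age_counts("X", "both", "all_four", rec))
  expect_equal(ser$rate, 1e5 * 30 / 8000)  # 375.0

  # identical band-level rate r aggregates to r
  r <- 250
  rec2 <- data.frame(year = 2000L, age_group = BANDS,
                     deaths = r / 1e5 * seq(1000, 8000, by = 1000),
                     population = seq(1000, 8000, by = 1000))
  ser2 <- compute_premature_rate(age_counts("X", "both", "all_four", rec2))
  expect_equal(ser2$rate, r, tolerance = 1e-12)
})

test_that("aggregation is order-invariant and scale-invariant", {
  set.seed(33)
  rec <- expand.grid(year = 2000:2004, age_group = BANDS,
                     stringsAsFactors = FALSE)
  rec$deaths <- sample(10:200, nrow(rec), replace = TRUE)
  rec$population <- sample(1e5:5e5, nrow(rec))
  base <- compute_premature_rate(age_counts("X", "both", "cvd", rec))
  shuf <- compute_premature_rate(
    age_counts("X", "both", "cvd", rec[sample.int(nrow(rec)), ]))
  expect_equal(shuf$rate, base$rate)
  scaled <- rec
  scaled$deaths <- scaled$deaths * 7
  scaled$population <- scaled$population * 7
  expect_equal(compute_premature_rate(
    age_counts("X", "both", "cvd", scaled))$rate, base$rate,
    tolerance = 1e-12)
})

test_that("incomplete age bands for a year raise a completeness error", {
  rec <- expand.grid(year = 2000:2001, age_group = BANDS,
                     stringsAsFactors = FALSE)
  rec$deaths <- 50
  rec$population <- 1e5
  rec <- rec[!(rec$year == 2001 & rec$age_group == "45-49"), ]
  err <- expect_error(
    compute_premature_rate(age_counts("X", "both", "cvd", rec)),
    class = "ncd_completeness_error")
  expect_match(conditionMessage(err), "2001")
  expect_match(conditionMessage(err), "45-49")
})

test_that("both-sex and combined cause groups are derived by summation", {
  path <- withr::local_tempfile(fileext = ".csv")
  set.seed(34)
  four <- c("cvd", "cancer", "diabetes", "chronic_resp")
  rows <- list()
  for (sx in c("male", "female")) {
    pop <- matrix(sample(3e5:5e5, 8), 1, 8)
    for (cs in four) {
      deaths <- matrix(sample(100:400, 8), 1, 8)
      rows[[paste(sx, cs)]] <- list(deaths = deaths, pop = pop)
    }
  }
  con <- file(path, "w")
  writeLines("measure,location,sex,age,cause,metric,year,val", con)
  for (sx in c("male", "female")) for (cs in four) {
    it <- rows[[paste(sx, cs)]]
    for (j in 1:8) {
      writeLines(sprintf("Deaths,L,%s,%s,%s,deaths,2000,%d", sx, BANDS[j],
                         cs, it$deaths[1, j]), con)
      writeLines(sprintf("Population,L,%s,%s,%s,population,2000,%d", sx,
                         BANDS[j], cs, it$pop[1, j]), con)
    }
  }
  close(con)
  counts <- read_gbd_results(path)
  # 8 direct groups + 4 both-sex + 3 all_four (male, female, both)
  expect_true("L/both/all_four" %in% names(counts))
  both_cvd <- counts[["L/both/cvd"]]$records
  expect_equal(sum(both_cvd$deaths),
               sum(rows[["male cvd"]]$deaths) + sum(rows[["female cvd"]]$deaths))
  all4_m <- counts[["L/male/all_four"]]$records
  expect_equal(sum(all4_m$deaths),
               sum(vapply(four, function(cs) sum(rows[[paste("male", cs)]]$deaths),
                          numeric(1))))
  # population is shared, not summed, across causes
  expect_equal(all4_m$population, counts[["L/male/cvd"]]$records$population)
})

test_that("validate_series enforces coverage, gaps and the rate domain", {
  s <- mortality_series("X", "both", "all_four", 1990:2019, rep(500, 30))
  expect_identical(validate_series(s, c(1990, 2019)), s)
  gap <- mortality_series("X", "both", "all_four",
                          setdiff(1990:2019, 2003), rep(500, 29))
  err <- expect_error(validate_series(gap), class = "ncd_gap_error")
  expect_match(conditionMessage(err), "2003")
  neg <- mortality_series("X", "both", "all_four", 1990:1999,
                          c(rep(500, 5), -1, rep(500, 4)))
  err2 <- expect_error(validate_series(neg), class = "ncd_domain_error")
  expect_match(conditionMessage(err2), "1995")
})
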