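# Ingestion of GBD-Results-Tool-style CSV exports and construction of crude
# premature (30-69) mortality rate series per 100,000.

# Canonical 5-year age bands spanning ages 30-69.
AGE_BANDS <- c("30-34", "35-39", "40-44", "45-49",
               "50-54", "55-59", "60-64", "65-69")

# Canonical cause-group keys and the GBD labels they match.
CAUSE_MAP <- c(
  "cardiovascular diseases"      = "cvd",
  "neoplasms"                    = "cancer",
  "diabetes mellitus"            = "diabetes",
  "chronic respiratory diseases" = "chronic_resp",
  "all four ncds"                = "all_four",
  "cvd" = "cvd", "cancer" = "cancer", "diabetes" = "diabetes",
  "chronic_resp" = "chronic_resp", "all_four" = "all_four"
)

SEX_MAP <- c("male" = "male", "female" = "female", "both" = "both",
             "males" = "male", "females" = "female", "both sexes" = "both")

#' Column mapping for GBD Results Tool exports
#'
#' Describes how the columns of a Results-Tool-style CSV map onto the fields
#' the ingest step needs, and how the `metric` column distinguishes death
#' counts from population counts. Only the point estimate column (`val`) is
#' used; `upper`/`lower` uncertainty columns are ignored if present.
#'
#' @param location,sex,cause,age,year,metric,value Column names in the CSV.
#' @param deaths_label,population_label Values of the `metric` column (matched
#'   case-insensitively) identifying death-count and population-count rows.
#' @return A named list usable as the `schema` argument of
#'   [read_gbd_results()].
#' @export
#' @examples
#' gbd_schema(value = "val")
gbd_schema <- function(location = "location", sex = "sex", cause = "cause",
                       age = "age", year = "year", metric = "metric",
                       value = "val", deaths_label = "deaths",
                       population_label = "population") {
  list(location = location, sex = sex, cause = cause, age = age,
       year = year, metric = metric, value = value,
       deaths_label = deaths_label, population_label = population_label)
}

# Normalize an age label: "30 to 34", "30–34 years" -> "30-34".
normalize_age_label <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("years?", "", x)
  x <- gsub("\\s*to\\s*", "-", x)
  x <- gsub("–|—", "-", x)
  x <- gsub("\\s+", "", x)
  x
}

normalize_sex_label <- function(x) {
  x <- tolower(trimws(x))
  out <- unname(SEX_MAP[x])
  ifelse(is.na(out), x, out)
}

normalize_cause_label <- function(x) {
  x <- tolower(trimws(x))
  out <- unname(CAUSE_MAP[x])
  ifelse(is.na(out), x, out)
}

#' Age-stratified death and population counts
#'
#' Container for annual deaths and population by 5-year age band (30-34
#' through 65-69) for one (location, sex, cause-group) combination.
#'
#' @param location Location label.
#' @param sex One of `"male"`, `"female"`, `"both"`.
#' @param cause Cause-group key, e.g. `"cvd"` or `"all_four"`.
#' @param records Data frame with columns `year`, `age_group`, `deaths`,
#'   `population`.
#' @return An object of class `age_counts`.
#' @export
age_counts <- function(location, sex, cause, records) {
  stopifnot(is.data.frame(records),
            all(c("year", "age_group", "deaths", "population") %in%
                  names(records)))
  records$age_group <- normalize_age_label(records$age_group)
  if (anyDuplicated(records[c("year", "age_group")]))
    abort_ncd("duplicate (year, age_group) records", "ncd_integrity_error")
  if (any(records$deaths < 0))
    abort_ncd("negative death counts", "ncd_domain_error")
  if (any(records$population <= 0))
    abort_ncd("non-positive population counts", "ncd_domain_error")
  if (any(records$deaths > records$population))
    abort_ncd("deaths exceed population in some records", "ncd_domain_error")
  yrs <- sort(unique(records$year))
  if (length(yrs) > 1L && !all(diff(yrs) == 1L))
    abort_ncd(sprintf("years are not a contiguous annual range (gap after %d)",
                      yrs[which(diff(yrs) != 1L)[1L]]),
              "ncd_gap_error")
  structure(list(location = location, sex = sex, cause = cause,
                 records = records[order(records$year, records$age_group), ,
                                   drop = FALSE]),
            class = "age_counts")
}

#' @export
print.age_counts <- function(x, ...) {
  cat(sprintf("Age-stratified counts: %s / %s / %s\n", x$location, x$sex,
              x$cause))
  cat(sprintf("  years %d-%d, %d records, %d age bands\n",
              min(x$records$year), max(x$records$year), nrow(x$records),
              length(unique(x$records$age_group))))
  invisible(x)
}

#' Read a GBD Results Tool CSV export
#'
#' Parses a long-format CSV with one row per (location, sex, cause, age band,
#' year, metric) and returns age-stratified counts per (location, sex,
#' cause-group). Rows for age bands outside 30-69 are dropped with a warning.
#' Sex `"both"` and the combined four-NCD cause group are derived by summation
#' when not present in the file.
#'
#' @param path Path to the CSV file (UTF-8, header row).
#' @param schema Column mapping from [gbd_schema()].
#' @param derive_both_sexes Derive a `"both"` sex stratum by summing male and
#'   female deaths and populations when `"both"` is absent.
#' @param derive_all_four Derive the combined `"all_four"` cause group by
#'   summing the four cause-specific death counts over the shared population
#'   when absent.
#' @return A list of [age_counts()] objects, named
#'   `"location/sex/cause"`.
#' @export
read_gbd_results <- function(path, schema = gbd_schema(),
                             derive_both_sexes = TRUE,
                             derive_all_four = TRUE) {
  if (!file.exists(path))
    abort_ncd(sprintf("file not found: %s", path), "ncd_io_error")
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c(location = schema$location, sex = schema$sex,
              cause = schema$cause, age = schema$age, year = schema$year,
              metric = schema$metric, value = schema$value)
  missing_cols <- needed[!needed %in% names(raw)]
  if (length(missing_cols))
    abort_ncd(sprintf("missing required column(s): %s",
                      paste(missing_cols, collapse = ", ")),
              "ncd_schema_error")
  d <- data.frame(location = as.character(raw[[schema$location]]),
                  sex = normalize_sex_label(raw[[schema$sex]]),
                  cause = normalize_cause_label(raw[[schema$cause]]),
                  age = normalize_age_label(raw[[schema$age]]),
                  year = as.integer(raw[[schema$year]]),
                  metric = tolower(trimws(raw[[schema$metric]])),
                  value = suppressWarnings(as.numeric(raw[[schema$value]])),
                  stringsAsFactors = FALSE)
  bad <- which(is.na(d$value))
  if (length(bad))
    abort_ncd(sprintf("non-numeric value field in row(s): %s",
                      paste(head(bad, 5L), collapse = ", ")),
              "ncd_parse_error")

  off_range <- !(d$age %in% AGE_BANDS)
  if (any(off_range)) {
    warn_ncd(sprintf("ignoring %d row(s) with age bands outside 30-69: %s",
                     sum(off_range),
                     paste(unique(d$age[off_range]), collapse = ", ")),
             "ncd_age_range_warning")
    d <- d[!off_range, , drop = FALSE]
  }

  is_death <- d$metric == tolower(schema$deaths_label)
  is_pop <- d$metric == tolower(schema$population_label)
  if (!any(is_death))
    abort_ncd("no death rows found (check the metric column)",
              "ncd_schema_error")
  d <- d[is_death | is_pop, , drop = FALSE]
  d$metric <- ifelse(d$metric == tolower(schema$deaths_label),
                     "deaths", "population")

  # Duplicate cells with conflicting values are an integrity failure.
  key <- with(d, paste(location, sex, cause, age, year, metric, sep = "|"))
  if (anyDuplicated(key)) {
    dup <- split(d$value, key)
    conflict <- names(dup)[vapply(dup, function(v)
      length(v) > 1L && max(v) - min(v) > 1e-8 * max(1, abs(max(v))),
      logical(1))]
    if (length(conflict))
      abort_ncd(sprintf("conflicting duplicate records: %s",
                        paste(head(conflict, 3L), collapse = "; ")),
                "ncd_integrity_error")
    d <- d[!duplicated(key), , drop = FALSE]
  }

  # Population is shared across cause groups; if it appears only under some
  # cause label (or a blank one), recycle it to every cause within
  # (location, sex).
  pop <- d[d$metric == "population", , drop = FALSE]
  dth <- d[d$metric == "deaths", , drop = FALSE]

  groups <- unique(dth[c("location", "sex", "cause")])
  out <- list()
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    gd <- dth[dth$location == g$location & dth$sex == g$sex &
                dth$cause == g$cause, , drop = FALSE]
    gp <- pop[pop$location == g$location & pop$sex == g$sex &
                pop$cause == g$cause, , drop = FALSE]
    if (!nrow(gp))  # fall back to any population stratum for this loc/sex
      gp <- pop[pop$location == g$location & pop$sex == g$sex, , drop = FALSE]
    m <- merge(gd[c("year", "age", "value")], gp[c("year", "age", "value")],
               by = c("year", "age"), all.x = TRUE,
               suffixes = c("_deaths", "_pop"))
    if (anyNA(m$value_pop)) {
      yrs <- sort(unique(m$year[is.na(m$value_pop)]))
      abort_ncd(sprintf(
        "no population counts for %s/%s/%s in year(s): %s",
        g$location, g$sex, g$cause, paste(yrs, collapse = ", ")),
        "ncd_integrity_error")
    }
    out[[paste(g$location, g$sex, g$cause, sep = "/")]] <-
      age_counts(g$location, g$sex, g$cause,
                 data.frame(year = m$year, age_group = m$age,
                            deaths = m$value_deaths,
                            population = m$value_pop,
                            stringsAsFactors = FALSE))
  }

  if (derive_both_sexes) out <- derive_both_sex_counts(out)
  if (derive_all_four) out <- derive_all_four_counts(out)
  out
}

# Sum male + female deaths and populations where "both" is absent.
derive_both_sex_counts <- function(counts) {
  meta <- do.call(rbind, lapply(counts, function(x)
    data.frame(location = x$location, sex = x$sex, cause = x$cause,
               stringsAsFactors = FALSE)))
  pairs <- unique(meta[c("location", "cause")])
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    have_both <- any(meta$location == p$location & meta$cause == p$cause &
                       meta$sex == "both")
    if (have_both) next
    km <- paste(p$location, "male", p$cause, sep = "/")
    kf <- paste(p$location, "female", p$cause, sep = "/")
    if (!km %in% names(counts) || !kf %in% names(counts)) next
    rm_ <- counts[[km]]$records
    rf <- counts[[kf]]$records
    m <- merge(rm_, rf, by = c("year", "age_group"),
               suffixes = c("_m", "_f"))
    counts[[paste(p$location, "both", p$cause, sep = "/")]] <-
      age_counts(p$location, "both", p$cause,
                 data.frame(year = m$year, age_group = m$age_group,
                            deaths = m$deaths_m + m$deaths_f,
                            population = m$population_m + m$population_f,
                            stringsAsFactors = FALSE))
  }
  counts
}

# Sum the four cause-specific death counts over the shared population where
# the combined group is absent.
derive_all_four_counts <- function(counts) {
  four <- c("cvd", "cancer", "diabetes", "chronic_resp")
  meta <- do.call(rbind, lapply(counts, function(x)
    data.frame(location = x$location, sex = x$sex, cause = x$cause,
               stringsAsFactors = FALSE)))
  pairs <- unique(meta[c("location", "sex")])
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    sub <- meta[meta$location == p$location & meta$sex == p$sex, ]
    if ("all_four" %in% sub$cause || !all(four %in% sub$cause)) next
    keys <- paste(p$location, p$sex, four, sep = "/")
    recs <- lapply(counts[keys], `[[`, "records")
    base <- recs[[1L]][c("year", "age_group", "population")]
    deaths <- recs[[1L]]$deaths
    for (j in 2:4) {
      m <- merge(base, recs[[j]][c("year", "age_group", "deaths")],
                 by = c("year", "age_group"), sort = FALSE)
      # merge(sort = FALSE) preserves base row order for matched keys
      deaths <- deaths + m$deaths[match(paste(base$year, base$age_group),
                                        paste(m$year, m$age_group))]
    }
    counts[[paste(p$location, p$sex, "all_four", sep = "/")]] <-
      age_counts(p$location, p$sex, "all_four",
                 data.frame(year = base$year, age_group = base$age_group,
                            deaths = deaths, population = base$population,
                            stringsAsFactors = FALSE))
  }
  counts
}

#' Annual crude mortality rate series
#'
#' @param location,sex,cause Series identity labels.
#' @param years Integer vector of calendar years, strictly increasing.
#' @param rate Numeric vector of crude rates per 100,000, same length as
#'   `years`.
#' @return An object of class `mortality_series`.
#' @export
mortality_series <- function(location, sex, cause, years, rate) {
  years <- as.integer(years)
  rate <- as.numeric(rate)
  if (length(years) != length(rate))
    abort_ncd("years and rate must have equal length", "ncd_domain_error")
  if (length(years) > 1L && any(diff(years) <= 0L))
    abort_ncd("years must be strictly increasing", "ncd_domain_error")
  if (any(!is.finite(rate)))
    abort_ncd("rates must be finite", "ncd_domain_error")
  structure(list(location = location, sex = sex, cause = cause,
                 years = years, rate = rate),
            class = "mortality_series")
}

#' @export
print.mortality_series <- function(x, ...) {
  cat(sprintf("Mortality series: %s / %s / %s\n", x$location, x$sex, x$cause))
  cat(sprintf("  %d-%d (n = %d), rate %.1f-%.1f per 100,000\n",
              min(x$years), max(x$years), length(x$years),
              min(x$rate), max(x$rate)))
  invisible(x)
}

#' @export
as.data.frame.mortality_series <- function(x, ...) {
  data.frame(location = x$location, sex = x$sex, cause = x$cause,
             year = x$years, rate = x$rate, stringsAsFactors = FALSE)
}

series_id <- function(series) {
  paste(series$location, series$sex, series$cause, sep = "/")
}

#' Crude premature (30-69) mortality rate per 100,000
#'
#' Sums deaths over the eight 5-year age bands 30-34 through 65-69 for each
#' year and divides by the summed population of the same bands, scaled to
#' 100,000: `rate = 1e5 * sum(deaths) / sum(population)`.
#'
#' @param counts An [age_counts()] object, or a list of them.
#' @return A `mortality_series` (or a list of them, matching the input).
#' @export
#' @examples
#' rec <- expand.grid(year = 2000:2001, age_group = c(
#'   "30-34","35-39","40-44","45-49","50-54","55-59","60-64","65-69"))
#' rec$deaths <- 50; rec$population <- 10000
#' compute_premature_rate(age_counts("X", "both", "all_four", rec))
compute_premature_rate <- function(counts) {
  if (!inherits(counts, "age_counts") && is.list(counts))
    return(lapply(counts, compute_premature_rate))
  stopifnot(inherits(counts, "age_counts"))
  rec <- counts$records
  years <- sort(unique(rec$year))
  for (y in years) {
    bands <- rec$age_group[rec$year == y]
    miss <- setdiff(AGE_BANDS, bands)
    if (length(miss))
      abort_ncd(sprintf("year %d lacks age band(s): %s", y,
                        paste(miss, collapse = ", ")),
                "ncd_completeness_error")
  }
  agg_d <- tapply(rec$deaths, rec$year, sum)
  agg_p <- tapply(rec$population, rec$year, sum)
  mortality_series(counts$location, counts$sex, counts$cause,
                   years = as.integer(names(agg_d)),
                   rate = 1e5 * as.numeric(agg_d) / as.numeric(agg_p))
}

#' Validate a mortality series for trend fitting
#'
#' Checks that the series covers a required span of years with no gaps and
#' has no negative rates; returns it unchanged.
#'
#' @param series A `mortality_series`.
#' @param required_span Optional `c(first_year, last_year)` that must be
#'   covered.
#' @return The input series, invisibly, if valid.
#' @export
validate_series <- function(series, required_span = NULL) {
  stopifnot(inherits(series, "mortality_series"))
  yrs <- series$years
  if (length(yrs) > 1L) {
    gaps <- setdiff(seq(min(yrs), max(yrs)), yrs)
    if (length(gaps))
      abort_ncd(sprintf("series has gap year(s): %s",
                        paste(gaps, collapse = ", ")), "ncd_gap_error")
  }
  if (!is.null(required_span)) {
    need <- seq(required_span[1L], required_span[2L])
    miss <- setdiff(need, yrs)
    if (length(miss))
      abort_ncd(sprintf("series does not cover required span; missing: %s",
                        paste(miss, collapse = ", ")), "ncd_gap_error")
  }
  if (any(series$rate < 0)) {
    bad <- yrs[series$rate < 0]
    abort_ncd(sprintf("negative rate in year(s): %s",
                      paste(bad, collapse = ", ")), "ncd_domain_error")
  }
  invisible(series)
}

#' Write rate series to a tidy CSV
#'
#' One row per (location, sex, cause, year) with the rate at full precision.
#'
#' @param series A `mortality_series` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rates_csv <- function(series, path) {
  if (inherits(series, "mortality_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, as.data.frame))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tidy rates CSV back into mortality series
#'
#' @param path CSV with columns location, sex, cause, year, rate.
#' @return Named list of `mortality_series`.
#' @export
read_rates_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("location", "sex", "cause", "year", "rate")
  if (!all(need %in% names(df)))
    abort_ncd(sprintf("rates CSV must have columns: %s",
                      paste(need, collapse = ", ")), "ncd_schema_error")
  sp <- split(df, paste(df$location, df$sex, df$cause, sep = "/"))
  lapply(sp, function(g) {
    g <- g[order(g$year), ]
    mortality_series(g$location[1L], g$sex[1L], g$cause[1L], g$year, g$rate)
  })
}
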