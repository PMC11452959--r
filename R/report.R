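# Table-style reports and trend figures, plus loaders for the published
# reference estimates shipped with the package.

#' Render a period table from segmented fits
#'
#' One row per series; for each period the start year, the fitted start rate
#' (1 decimal) and the signed percent change (1 decimal), ending with the
#' final year and rate. The column count adapts to the largest period count
#' among the fits; series with fewer periods leave trailing cells empty.
#'
#' @param fits A named list of `segtrend` fits (or one fit).
#' @return Data frame of character cells, one row per series.
#' @export
render_period_table <- function(fits) {
  if (inherits(fits, "segtrend")) fits <- list(fits)
  summaries <- lapply(fits, summarize_periods)
  kmax <- max(vapply(summaries, nrow, integer(1)))
  rows <- lapply(seq_along(fits), function(i) {
    ps <- summaries[[i]]
    cells <- character(0)
    for (k in seq_len(kmax)) {
      if (k <= nrow(ps))
        cells <- c(cells, as.character(ps$start_year[k]),
                   fmt1(ps$start_rate[k]), fmt_pct(ps$pct_change[k]))
      else cells <- c(cells, "", "", "")
    }
    last <- nrow(ps)
    cells <- c(cells, as.character(ps$end_year[last]),
               fmt1(ps$end_rate[last]))
    nm <- names(fits)[i]
    if (is.null(nm) || !nzchar(nm)) nm <- series_id(fits[[i]]$series)
    c(series = nm, cells)
  })
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("series",
                  as.vector(t(outer(seq_len(kmax), c("year", "rate", "change"),
                                    function(k, w) paste0(w, "_", k)))),
                  "final_year", "final_rate")
  rownames(out) <- NULL
  out
}

#' Render an assessment table
#'
#' One row per series with `"point [lo-hi]"` prediction cells (1 decimal,
#' en-dash separator by default) and `"target (Category)"` cells for each
#' horizon present. Requires both horizons for every series.
#'
#' @param assessments Data frame from [assess_all()] (or rows of the same
#'   shape).
#' @param dash Interval separator (defaults to an en-dash).
#' @return Data frame of character cells.
#' @export
render_assessment_table <- function(assessments, dash = "–") {
  need <- c("id", "horizon_year", "point", "lo", "hi", "target_level",
            "category")
  if (!all(need %in% names(assessments)))
    abort_ncd("assessments lack required columns", "ncd_schema_error")
  horizons <- sort(unique(assessments$horizon_year))
  ids <- unique(assessments$id)
  rows <- lapply(ids, function(id) {
    sub <- assessments[assessments$id == id, ]
    cells <- c(series = id)
    for (h in horizons) {
      r <- sub[sub$horizon_year == h, ]
      if (!nrow(r))
        abort_ncd(sprintf("series %s lacks horizon %d", id, h),
                  "ncd_completeness_error")
      cells <- c(cells,
                 sprintf("%s [%s%s%s]", fmt1(r$point), fmt1(r$lo), dash,
                         fmt1(r$hi)),
                 sprintf("%s (%s)", fmt1(r$target_level), r$category))
    }
    cells
  })
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("series",
                  as.vector(t(outer(horizons, c("predicted", "target"),
                                    function(h, w) paste0(w, "_", h)))))
  rownames(out) <- NULL
  out
}

#' Plot a segmented trend fit
#'
#' Observed rates as points, the fitted piecewise linear mean drawn segment
#' by segment (so level jumps are visible), optional forecasts with interval
#' bars, and optional horizontal target-level markers.
#'
#' @param x A `segtrend` fit.
#' @param forecasts Optional data frame from [forecast_rate()] or rows of
#'   [assess_all()] (columns `horizon_year`, `point`, `lo`, `hi`).
#' @param targets Optional numeric target levels, drawn as dashed lines.
#' @param main Plot title.
#' @param ... Further arguments to `plot()`.
#' @return The fit, invisibly.
#' @export
plot.segtrend <- function(x, forecasts = NULL, targets = NULL,
                          main = series_id(x$series), ...) {
  xmax <- if (!is.null(forecasts)) max(forecasts$horizon_year)
          else max(x$years)
  yvals <- c(x$y, x$fitted.values, forecasts$lo, forecasts$hi, targets)
  plot(x$years, x$y, pch = 16, cex = 0.7, xlim = c(min(x$years), xmax),
       ylim = range(yvals, na.rm = TRUE), xlab = "year",
       ylab = "rate per 100,000", main = main, ...)
  bounds <- c(min(x$years), x$changepoints, max(x$years) + 1L)
  for (k in seq_len(length(bounds) - 1L)) {
    yrs <- x$years[x$years >= bounds[k] & x$years < bounds[k + 1L]]
    lines(yrs, drop(.design_at(x, yrs) %*% x$coefficients), lwd = 2,
          col = "steelblue")
  }
  if (length(x$changepoints))
    abline(v = x$changepoints, col = "grey70", lty = 3)
  if (!is.null(forecasts)) {
    points(forecasts$horizon_year, forecasts$point, pch = 17,
           col = "firebrick")
    arrows(forecasts$horizon_year, forecasts$lo, forecasts$horizon_year,
           forecasts$hi, angle = 90, code = 3, length = 0.05,
           col = "firebrick")
  }
  if (!is.null(targets))
    abline(h = targets, lty = 2, col = "darkgreen")
  invisible(x)
}

#' Write a trend figure to an SVG file
#'
#' Renders [plot.segtrend()] into an SVG. The output is a pure function of
#' the inputs (no timestamps), so identical calls produce identical bytes; a
#' reproducible configuration hash of the inputs is appended as an XML
#' comment.
#'
#' @param fit A `segtrend` fit.
#' @param file Output file path (`.svg`).
#' @param forecasts,targets See [plot.segtrend()].
#' @param width,height Device size in inches.
#' @return `file`, invisibly.
#' @export
plot_trends <- function(fit, file, forecasts = NULL, targets = NULL,
                        width = 7, height = 5) {
  svg(file, width = width, height = height)
  ok <- FALSE
  tryCatch({
    plot(fit, forecasts = forecasts, targets = targets)
    ok <- TRUE
  }, finally = dev.off())
  if (!ok) abort_ncd("figure rendering failed", "ncd_io_error")
  hash <- config_hash(list(series = fit$series, changepoints = fit$changepoints,
                           coefficients = fit$coefficients,
                           forecasts = forecasts, targets = targets))
  cat(sprintf("<!-- ncdtrend-config-hash: %s -->\n", hash), file = file,
      append = TRUE)
  invisible(file)
}

#' Read the configuration hash stamped on a figure file
#'
#' @param file An SVG written by [plot_trends()].
#' @return The 8-hex-digit hash, or `NA` if absent.
#' @export
figure_config_hash <- function(file) {
  lines <- readLines(file, warn = FALSE)
  m <- regmatches(lines, regexpr("ncdtrend-config-hash: ([0-9a-f]{8})",
                                 lines))
  if (!length(m)) return(NA_character_)
  sub("ncdtrend-config-hash: ", "", m[[1L]])
}

#' Published period estimates for twelve Eastern European and Central Asian
#' countries
#'
#' Piecewise-linear trend estimates of total premature NCD mortality
#' (ages 30-69, per 100,000) over 1990-2019 for Armenia, Azerbaijan,
#' Belarus, Georgia, Kazakhstan, Kyrgyzstan, Moldova, Russia, Tajikistan,
#' Turkmenistan, Uzbekistan and Ukraine: per period the boundary years,
#' fitted boundary rates and percent change.
#'
#' @return Data frame with columns `country`, `period`, `start_year`,
#'   `start_rate`, `pct_change`, `end_year`, `end_rate`.
#' @export
eeca_trend_periods <- function() {
  read.csv(system.file("extdata", "eeca_trend_periods.csv",
                       package = "ncdtrend"), stringsAsFactors = FALSE)
}

#' Published forecasts and target assessments for the twelve countries
#'
#' Predicted total premature NCD mortality rates for 2025 and 2030 with 95%
#' intervals, the WHO 25x25 and SDG 3.4.1 target levels, and the published
#' likelihood category for each.
#'
#' @return Data frame with columns `country`, `horizon`, `point`, `lo`,
#'   `hi`, `target`, `published_category`.
#' @export
eeca_target_assessments <- function() {
  read.csv(system.file("extdata", "eeca_target_assessments.csv",
                       package = "ncdtrend"), stringsAsFactors = FALSE)
}
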