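# Period summaries of a segmented fit: the spans between consecutive change
# points, with fitted boundary rates and percent changes.

#' Percent change between two rates
#'
#' `100 * (end_rate - start_rate) / start_rate`.
#'
#' @param start_rate Positive starting rate.
#' @param end_rate Ending rate.
#' @return Percent change (unrounded; reports round to 1 decimal).
#' @export
#' @examples
#' percent_change(562.0, 672.3)  # +19.6 after 1-decimal rounding
percent_change <- function(start_rate, end_rate) {
  if (any(start_rate <= 0))
    abort_ncd("start_rate must be positive", "ncd_domain_error")
  100 * (end_rate - start_rate) / start_rate
}

#' Period summaries of a segmented trend fit
#'
#' The change points partition the observed years into consecutive periods;
#' period k ends at the year of change point k and period k+1 starts at that
#' same year, so adjacent periods share their boundary year. Boundary rates
#' are the fitted mean evaluated at the boundary years (the fitted mean is
#' right-continuous at a change point, so the shared boundary carries a
#' single rate, as in published period tables).
#'
#' @param fit A `segtrend` object.
#' @return Data frame with columns `period`, `start_year`, `start_rate`,
#'   `end_year`, `end_rate`, `pct_change` (unrounded).
#' @export
summarize_periods <- function(fit) {
  stopifnot(inherits(fit, "segtrend"))
  bounds <- c(min(fit$years), fit$changepoints, max(fit$years))
  mean_at <- function(yr) drop(.design_at(fit, yr) %*% fit$coefficients)
  k <- length(bounds) - 1L
  data.frame(
    period = seq_len(k),
    start_year = bounds[-length(bounds)],
    start_rate = mean_at(bounds[-length(bounds)]),
    end_year = bounds[-1L],
    end_rate = mean_at(bounds[-1L]),
    pct_change = percent_change(mean_at(bounds[-length(bounds)]),
                                mean_at(bounds[-1L]))
  )
}

# Segmented design rows for arbitrary calendar years, using the fit's time
# origin and change points (indicators stay switched on past the data end,
# so extrapolation follows the final segment's line).
.design_at <- function(fit, years) {
  y0 <- fit$years[1L]
  X <- cbind(1, years - y0)
  for (c in fit$changepoints) {
    ind <- as.numeric(years >= c)
    X <- cbind(X, ind, ind * (years - c))
  }
  colnames(X) <- names(fit$coefficients)
  X
}
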