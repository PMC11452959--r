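# Segmented (piecewise linear) design construction and change-point
# candidate enumeration.

#' Validate a set of change-point years
#'
#' Change points must be sorted calendar years lying strictly inside the
#' observed range with at least `edge_margin` observations strictly before
#' and strictly after each, and consecutive change points must be at least
#' `min_gap` years apart.
#'
#' @param years Observed annual year vector.
#' @param changepoints Candidate change-point years (0 to 3 of them).
#' @param min_gap Minimum spacing between change points, in years.
#' @param edge_margin Minimum number of observations strictly on each side of
#'   every change point.
#' @return The change points, sorted, invisibly.
#' @export
validate_changepoints <- function(years, changepoints, min_gap = 3,
                                  edge_margin = 3) {
  cps <- sort(as.integer(changepoints))
  if (!length(cps)) return(invisible(cps))
  for (c in cps) {
    before <- sum(years < c)
    after <- sum(years > c)
    if (before < edge_margin || after < edge_margin)
      abort_ncd(sprintf(
        "change point %d leaves fewer than %d observations on one side",
        c, edge_margin), "ncd_changepoint_error")
  }
  if (length(cps) > 1L && any(diff(cps) < min_gap))
    abort_ncd(sprintf("change points closer than %d years: %s", min_gap,
                      paste(cps, collapse = ", ")), "ncd_changepoint_error")
  invisible(cps)
}

#' Design matrix for a piecewise linear trend with level and slope changes
#'
#' Time is coded as `t = year - first_year`. The design has a global
#' intercept and slope column, plus, for each change point `c` (expressed in
#' calendar years), a step column `1(year >= c)` and a slope-change column
#' `(year - c) * 1(year >= c)`. A change point therefore allows both a jump
#' in level and a change in slope.
#'
#' @inheritParams validate_changepoints
#' @return Numeric matrix with `2 + 2 * length(changepoints)` columns, named
#'   `(Intercept)`, `t`, and `step<c>` / `slope<c>` per change point.
#' @export
#' @examples
#' build_segmented_design(1990:1999, 1995)
build_segmented_design <- function(years, changepoints = integer(0)) {
  years <- as.integer(years)
  cps <- sort(as.integer(changepoints))
  t <- years - years[1L]
  X <- cbind("(Intercept)" = 1, t = t)
  for (c in cps) {
    ind <- as.numeric(years >= c)
    X <- cbind(X, ind, ind * (years - c))
    colnames(X)[ncol(X) - 1:0] <- paste0(c("step", "slope"), c)
  }
  if (qr(X)$rank < ncol(X))
    abort_ncd("segmented design is rank deficient", "ncd_design_error")
  X
}

#' Candidate change-point years under the edge-margin rule
#'
#' @inheritParams validate_changepoints
#' @return Integer vector of admissible single change-point years.
#' @export
candidate_changepoints <- function(years, edge_margin = 3) {
  years <- as.integer(years)
  n <- length(years)
  if (n < 2L * edge_margin + 1L) return(integer(0))
  years[(edge_margin + 1L):(n - edge_margin)]
}

#' Enumerate admissible change-point sets
#'
#' All subsets of the candidate years of size `0..max_cp` (or exactly
#' `exact_k` when given) whose elements are pairwise at least `min_gap` years
#' apart.
#'
#' @inheritParams validate_changepoints
#' @param max_cp Maximum number of change points.
#' @param exact_k If given, enumerate only sets of exactly this size.
#' @return List of integer vectors of change-point years (the first element
#'   is the empty set unless `exact_k` is given).
#' @export
enumerate_changepoint_sets <- function(years, max_cp = 2, min_gap = 3,
                                       edge_margin = 3, exact_k = NULL) {
  cand <- candidate_changepoints(years, edge_margin)
  ks <- if (is.null(exact_k)) 0:max_cp else exact_k
  out <- list()
  for (k in ks) {
    if (k == 0L) { out <- c(out, list(integer(0))); next }
    if (length(cand) < k) next
    sets <- combn(cand, k, simplify = FALSE)
    ok <- vapply(sets, function(s) k == 1L || all(diff(s) >= min_gap),
                 logical(1))
    out <- c(out, sets[ok])
  }
  if (!length(out))
    abort_ncd("no admissible change-point sets under the given constraints",
              "ncd_config_error")
  out
}
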