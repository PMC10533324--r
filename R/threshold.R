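#' Fixed-threshold classification rule
#'
#' The simplest classifier: a concentration at or above the threshold is
#' called pregnant. The canonical thresholds are 100 ng per g of tissue and
#' approximately 150 ng per g of lipid, chosen from a natural break in the
#' observed concentration distributions (no values fell between 85.9 and 114
#' ng/g tissue in any sampling program). The boundary is inclusive-above:
#' a value exactly at the threshold is classified pregnant.
#'
#' @param threshold Positive concentration, ng per g (default 100 for tissue,
#'   150 for lipid when `threshold` is not supplied).
#' @param unit Reporting unit the rule applies to, `"tissue"` or `"lipid"`.
#' @return An object of class `threshold_rule`.
#' @export
#' @examples
#' threshold_rule()                 # 100 ng/g tissue
#' threshold_rule(unit = "lipid")   # 150 ng/g lipid
threshold_rule <- function(threshold = NULL, unit = c("tissue", "lipid")) {
  unit <- match.arg(unit)
  if (is.null(threshold)) threshold <- if (unit == "tissue") 100 else 150
  stop_if_not_scalar_number(threshold, "threshold")
  if (threshold <= 0) stop("`threshold` must be positive", call. = FALSE)
  structure(list(threshold = threshold, unit = unit, inclusive = TRUE),
            class = "threshold_rule")
}

#' Classify concentrations against a fixed threshold
#'
#' @param values Concentrations, ng per g, in the rule's unit (non-negative).
#' @param rule A [threshold_rule()].
#' @param unit Optional declaration of the unit `values` are expressed in;
#'   an explicit mismatch with `rule$unit` is an error.
#' @return Character vector of labels, `"pregnant"` or `"non_pregnant"`.
#' @export
#' @examples
#' classify_fixed_threshold(c(9, 413, 100), threshold_rule())
classify_fixed_threshold <- function(values, rule = threshold_rule(),
                                     unit = NULL) {
  stopifnot(inherits(rule, "threshold_rule"))
  if (!is.null(unit) && !identical(unit, rule$unit)) {
    stop(sprintf("values are per %s but the rule applies per %s",
                 unit, rule$unit), call. = FALSE)
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  ifelse(values >= rule$threshold, "pregnant", "non_pregnant")
}

#' Widest empty interval in a concentration distribution
#'
#' Scans consecutive order statistics of the observed values and returns the
#' pair with the largest spacing inside a search window, i.e. the widest
#' interval containing no observation — the "natural break" used to place a
#' fixed threshold. The window (default 1 to 1000 ng/g) keeps the trivially
#' enormous gap above the largest observation from being reported.
#'
#' @param values Concentrations with at least 2 distinct values.
#' @param window Numeric length-2 search window; only gaps whose endpoints
#'   both fall inside it are candidates.
#' @return Named numeric vector `c(lower, upper)`; no observation lies
#'   strictly inside the open interval.
#' @export
#' @examples
#' find_gap(c(1, 2, 10))
find_gap <- function(values, window = c(1, 1000)) {
  values <- values[is.finite(values)]
  v <- sort(unique(values))
  if (length(v) < 2) {
    stop("`values` must contain at least 2 distinct finite values",
         call. = FALSE)
  }
  stopifnot(is.numeric(window), length(window) == 2L, window[1] < window[2])
  lower <- v[-length(v)]
  upper <- v[-1]
  ok <- lower >= window[1] & upper <= window[2]
  if (!any(ok)) {
    stop("no candidate gap lies inside the search window; widen `window`",
         call. = FALSE)
  }
  widths <- upper - lower
  widths[!ok] <- -Inf
  i <- which.max(widths)
  c(lower = lower[i], upper = upper[i])
}
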