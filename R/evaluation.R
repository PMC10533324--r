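#' Expected dichotomous label for a known reproductive status
#'
#' Adjudication rule for scoring classifiers against necropsy truth: pregnant
#' females are expected pregnant, and recently parturient females are also
#' expected pregnant — their blubber progesterone is assumed to still carry
#' the signal of the pregnancy that just ended. Males (immature or mature),
#' immature females, resting and lactating females are expected non-pregnant.
#' An unknown status is an error: evaluation requires ground truth.
#'
#' @param status Character vector of known reproductive statuses.
#' @return Character vector of `"pregnant"` / `"non_pregnant"`.
#' @export
#' @examples
#' expected_label(c("recent_parturition", "lactating"))
expected_label <- function(status) {
  map <- c(pregnant = "pregnant", recent_parturition = "pregnant",
           immature_male = "non_pregnant", mature_male = "non_pregnant",
           immature_female = "non_pregnant", resting = "non_pregnant",
           lactating = "non_pregnant")
  bad <- is.na(status) | !status %in% names(map)
  if (any(bad)) {
    stop("cannot adjudicate status value(s): ",
         paste(unique(ifelse(is.na(status[bad]), "NA", status[bad])),
               collapse = ", "),
         " (evaluation requires a known reproductive status)", call. = FALSE)
  }
  unname(map[status])
}

#' Count misclassifications against expected labels
#'
#' Compares predicted labels to expected labels position by position.
#' Predictions of `"intermediate"` (the middle cluster of a three-component
#' mixture) are scored as non-pregnant for the dichotomous comparison: the
#' published pregnancy-rate arithmetic counts intermediates in the mature
#' denominator but not in the pregnant numerator, and this scoring mirrors
#' that.
#'
#' @param predicted,expected Equal-length character label vectors.
#' @param status Optional vector of true reproductive statuses, used for the
#'   per-status error breakdown.
#' @return List with `count` (number of disagreements), `confusion` (a
#'   predicted x expected table) and, when `status` is supplied, `by_status`
#'   (errors per true status).
#' @export
#' @examples
#' misclassification_count(c("pregnant", "non_pregnant"),
#'                         c("pregnant", "pregnant"))$count
misclassification_count <- function(predicted, expected, status = NULL) {
  if (length(predicted) != length(expected)) {
    stop("`predicted` and `expected` must have the same length",
         call. = FALSE)
  }
  pred <- ifelse(predicted %in% c("intermediate",
                                  paste0("intermediate_", 1:9)),
                 "non_pregnant", predicted)
  errors <- pred != expected
  out <- list(
    count = sum(errors),
    confusion = table(predicted = pred, expected = expected)
  )
  if (!is.null(status)) {
    if (length(status) != length(predicted)) {
      stop("`status` must align with the labels", call. = FALSE)
    }
    out$by_status <- tapply(errors, status, sum)
  }
  out
}

#' Fraction of assignments that switch between reporting units
#'
#' Compares the labels a classifier gives the same samples when BP is
#' expressed per g of tissue versus per g of lipid. Low-lipid samples are
#' where switching concentrates (observed switchers all had lipid fractions
#' below 10%), so per-sample switch flags are joined to the lipid fractions
#' when supplied.
#'
#' @param labels_tissue,labels_lipid Equal-length label vectors from the same
#'   samples under the two reporting units.
#' @param lipid_fraction Optional lipid fractions aligned with the labels.
#' @return List with `fraction` (share of samples switching), `switched`
#'   (logical per sample) and, when lipid fractions are supplied, `detail`
#'   (data frame of switch flags and lipid fractions).
#' @export
unit_switch_fraction <- function(labels_tissue, labels_lipid,
                                 lipid_fraction = NULL) {
  if (length(labels_tissue) != length(labels_lipid)) {
    stop("label vectors must be aligned (same samples, same order)",
         call. = FALSE)
  }
  switched <- labels_tissue != labels_lipid
  out <- list(
    fraction = if (length(switched)) mean(switched) else 0,
    switched = switched
  )
  if (!is.null(lipid_fraction)) {
    if (length(lipid_fraction) != length(switched)) {
      stop("`lipid_fraction` must align with the labels", call. = FALSE)
    }
    out$detail <- data.frame(switched = switched,
                             lipid_fraction = lipid_fraction)
  }
  out
}
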