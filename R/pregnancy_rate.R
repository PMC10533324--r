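#' Colour-class maturity schedule
#'
#' Beluga skin lightens with age (grey, then off-white, then white), but
#' colour is an imperfect proxy for sexual maturity. Necropsies of females
#' aged over three years give the canonical per-class maturity probabilities:
#' 100% of white and off-white females were mature, against 10% of grey
#' individuals. With a three-year reproductive cycle, about one-third of
#' mature females are expected to enter gestation each year
#' (`cycle_fraction = 1/3`).
#'
#' @param white,off_white,grey Maturity probabilities in \[0, 1\].
#' @param cycle_fraction Expected annual pregnancy fraction among mature
#'   females, in (0, 1].
#' @return An object of class `maturity_schedule`.
#' @export
#' @examples
#' maturity_schedule()
maturity_schedule <- function(white = 1, off_white = 1, grey = 0.1,
                              cycle_fraction = 1 / 3) {
  prob <- c(grey = grey, off_white = off_white, white = white)
  if (any(prob < 0) || any(prob > 1)) {
    stop("maturity probabilities must lie in [0, 1]", call. = FALSE)
  }
  stop_if_not_scalar_number(cycle_fraction, "cycle_fraction")
  if (cycle_fraction <= 0 || cycle_fraction > 1) {
    stop("`cycle_fraction` must lie in (0, 1]", call. = FALSE)
  }
  structure(list(prob = prob, cycle_fraction = cycle_fraction),
            class = "maturity_schedule")
}

#' Per-colour-class sample counts
#'
#' Records, for each colour class, how many females were biopsied and how
#' many were "virtually biopsied" (females repeatedly flanked by a newborn
#' calf that would have been darted but were not; they enter as lactating —
#' hence mature — individuals with no BP value, to avoid a sampling bias
#' against lactating females).
#'
#' @param colour_class Character vector of colour classes.
#' @param biopsied,virtual Non-negative counts aligned with `colour_class`.
#' @return A `data.frame` with one row per colour class.
#' @export
#' @examples
#' colour_counts(c("white", "off_white", "grey"),
#'               biopsied = c(30, 9, 12), virtual = c(3, 3, 3))
colour_counts <- function(colour_class, biopsied, virtual = 0) {
  stopifnot(length(colour_class) >= 1,
            length(biopsied) == length(colour_class))
  virtual <- rep_len(virtual, length(colour_class))
  if (any(biopsied < 0) || any(virtual < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (anyDuplicated(colour_class)) {
    stop("each colour class may appear only once", call. = FALSE)
  }
  data.frame(colour_class = colour_class, biopsied = biopsied,
             virtual = virtual, stringsAsFactors = FALSE)
}

schedule_prob <- function(schedule, classes) {
  missing <- setdiff(classes, names(schedule$prob))
  if (length(missing)) {
    stop("colour class(es) missing from the maturity schedule: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  schedule$prob[classes]
}

#' Expected number of mature females in a sample
#'
#' Applies the maturity schedule to each colour class: biopsied count times
#' the class maturity probability, plus the virtual-biopsy count (virtually
#' biopsied females are lactating, hence mature with probability 1). With
#' the canonical counts — 30 biopsied plus 3 virtual white, 9 plus 3
#' off-white, 12 plus 3 grey — this predicts 33 + 12 + 4.2 = 49.2, i.e. ~49
#' mature females out of 60.
#'
#' @param counts A [colour_counts()] data frame.
#' @param schedule A [maturity_schedule()] covering every class present.
#' @return List with `per_class` (audit data frame), `total` (unrounded) and
#'   `total_rounded` (nearest integer, halves away from zero).
#' @export
#' @examples
#' cc <- colour_counts(c("white", "off_white", "grey"), c(30, 9, 12), 3)
#' expected_mature_count(cc, maturity_schedule())
expected_mature_count <- function(counts, schedule = maturity_schedule()) {
  stopifnot(is.data.frame(counts), inherits(schedule, "maturity_schedule"))
  p <- schedule_prob(schedule, counts$colour_class)
  per_class <- data.frame(
    colour_class = counts$colour_class,
    biopsied = counts$biopsied,
    virtual = counts$virtual,
    maturity_prob = unname(p),
    expected_mature = counts$biopsied * unname(p) + counts$virtual,
    stringsAsFactors = FALSE
  )
  total <- sum(per_class$expected_mature)
  list(per_class = per_class, total = total,
       total_rounded = round_half_up(total))
}

#' Expected number of pregnant females among mature females
#'
#' `mature * cycle_fraction`, rounded to the nearest integer (halves away
#' from zero). With a three-year cycle, 49 mature females are expected to
#' include 16 pregnancies.
#'
#' @param mature Number of mature females (>= 0).
#' @param cycle_fraction Annual pregnancy fraction (default 1/3).
#' @return Rounded expected count, with the unrounded value as attribute
#'   `"unrounded"`.
#' @export
#' @examples
#' expected_pregnant_count(49)
expected_pregnant_count <- function(mature, cycle_fraction = 1 / 3) {
  stop_if_not_scalar_number(mature, "mature")
  if (mature < 0) stop("`mature` must be non-negative", call. = FALSE)
  raw <- mature * cycle_fraction
  structure(round_half_up(raw), unrounded = raw)
}

#' Maturity-adjusted population pregnancy rate
#'
#' The raw rate `n_pregnant / min_mature` uses only females known to be
#' mature (presumed pregnant, intermediate-cluster, and virtual lactating
#' females). Non-pregnant females of unknown maturity are then distributed by
#' colour class and the maturity schedule, adding
#' `round(sum(count_c * maturity_c))` females to the denominator. With the
#' canonical inputs (20 pregnant, 45 minimum mature, and 7 white, 3 off-white
#' and 5 grey non-pregnant females of unknown maturity) this shifts the rate
#' from 20/45 = 44.4% to 20/56 = 35.7%.
#'
#' @param n_pregnant Number of presumed-pregnant females.
#' @param min_mature Minimum number of mature females (>= `n_pregnant`, > 0).
#' @param nonpregnant_counts Named numeric vector (or [colour_counts()]-style
#'   data frame using its `biopsied` column) of non-pregnant,
#'   unknown-maturity females per colour class.
#' @param schedule A [maturity_schedule()].
#' @return An object of class `pregnancy_rate_estimate` with the numerator,
#'   raw and adjusted denominators and rates, and a per-class audit table.
#' @export
#' @examples
#' adjusted_pregnancy_rate(20, 45,
#'                         c(white = 7, off_white = 3, grey = 5),
#'                         maturity_schedule())
adjusted_pregnancy_rate <- function(n_pregnant, min_mature,
                                    nonpregnant_counts,
                                    schedule = maturity_schedule()) {
  stop_if_not_scalar_number(n_pregnant, "n_pregnant")
  stop_if_not_scalar_number(min_mature, "min_mature")
  if (min_mature <= 0) stop("`min_mature` must be positive (zero ",
                            "denominator)", call. = FALSE)
  if (n_pregnant < 0 || n_pregnant > min_mature) {
    stop("`n_pregnant` must lie in [0, min_mature]", call. = FALSE)
  }
  if (is.data.frame(nonpregnant_counts)) {
    counts <- stats::setNames(nonpregnant_counts$biopsied,
                              nonpregnant_counts$colour_class)
  } else {
    counts <- nonpregnant_counts
  }
  if (length(counts) && any(counts < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  p <- if (length(counts)) schedule_prob(schedule, names(counts)) else numeric(0)
  audit <- data.frame(
    colour_class = names(counts),
    nonpregnant = unname(counts),
    maturity_prob = unname(p),
    additional_mature = unname(counts * p),
    stringsAsFactors = FALSE
  )
  additional <- round_half_up(sum(audit$additional_mature))
  structure(
    list(n_pregnant = n_pregnant, min_mature = min_mature,
         additional_mature = additional,
         adjusted_denominator = min_mature + additional,
         raw_rate = n_pregnant / min_mature,
         adjusted_rate = n_pregnant / (min_mature + additional),
         audit = audit),
    class = "pregnancy_rate_estimate"
  )
}

#' Pregnancy-rate estimate from classified samples
#'
#' Convenience wrapper assembling the [adjusted_pregnancy_rate()] inputs from
#' a classified sample table: the numerator is the count of non-virtual
#' females labelled pregnant; the minimum-mature denominator adds
#' intermediate-cluster females and virtual (lactating) females; the
#' remaining non-pregnant, non-virtual females are distributed by colour
#' class for the maturity correction.
#'
#' @param samples Sample table with `colour_class` and `is_virtual` columns.
#' @param labels Classification labels aligned with `samples` (virtual rows
#'   may be `NA`; they are counted as mature non-pregnant).
#' @param schedule A [maturity_schedule()].
#' @return A `pregnancy_rate_estimate`.
#' @export
pregnancy_rate_from_labels <- function(samples, labels,
                                       schedule = maturity_schedule()) {
  stopifnot(is.data.frame(samples), nrow(samples) == length(labels))
  virt <- if (is.null(samples$is_virtual)) {
    rep(FALSE, nrow(samples))
  } else {
    isTRUE_vec(samples$is_virtual)
  }
  pregnant <- !virt & !is.na(labels) & labels == "pregnant"
  intermediate <- !virt & !is.na(labels) & grepl("^intermediate", labels)
  nonpreg <- !virt & !is.na(labels) & labels == "non_pregnant"
  n_pregnant <- sum(pregnant)
  min_mature <- n_pregnant + sum(intermediate) + sum(virt)
  counts_tab <- table(samples$colour_class[nonpreg])
  counts <- stats::setNames(as.numeric(counts_tab), names(counts_tab))
  adjusted_pregnancy_rate(n_pregnant, min_mature, counts, schedule)
}

isTRUE_vec <- function(x) {
  if (is.null(x)) return(logical(0))
  !is.na(x) & x
}

#' @export
print.pregnancy_rate_estimate <- function(x, ...) {
  cat("Pregnancy-rate estimate\n")
  cat(sprintf("  raw:      %d/%d = %.1f%%\n", x$n_pregnant, x$min_mature,
              100 * x$raw_rate))
  cat(sprintf("  adjusted: %d/%d = %.1f%% (+%d mature via colour-class ",
              x$n_pregnant, x$adjusted_denominator, 100 * x$adjusted_rate,
              x$additional_mature))
  cat("maturity correction)\n")
  invisible(x)
}
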