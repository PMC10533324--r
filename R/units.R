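#' Back-calculate a tissue concentration from a raw immunoassay reading
#'
#' Standard competitive-ELISA back-calculation: the assay reports pg/mL of
#' resuspended extract; multiplying by the resuspension buffer volume and the
#' dilution factor gives total pg extracted, dividing by 1000 converts to ng,
#' and dividing by the extraction recovery fraction and the wet blubber mass
#' yields ng per g of tissue:
#' `(raw * buffer_volume * dilution_factor / 1000) / (recovery_fraction * blubber_mass)`.
#' Extraction efficiency was 88.3% for the carcass assays and 71.0% for the
#' biopsy assays; the extract is resuspended in 500 uL of assay buffer, hence
#' the 0.5 mL default.
#'
#' @param raw_concentration Assay reading, pg/mL (non-negative; vectorised).
#' @param buffer_volume Resuspension volume, mL (default 0.5).
#' @param dilution_factor Dilution applied to bring the sample onto the
#'   standard curve; >= 1 (assays here used factors of 5 to 5000).
#' @param recovery_fraction Extraction efficiency in (0, 1]; measured
#'   concentrations are divided by it.
#' @param blubber_mass Wet mass of the extracted blubber subsample, g (> 0).
#' @return Concentration in ng per g of tissue.
#' @export
#' @examples
#' adjust_assay_concentration(100, buffer_volume = 0.5, dilution_factor = 1,
#'                            recovery_fraction = 1, blubber_mass = 0.1)
#' # with the carcass-assay recovery of 88.3%
#' adjust_assay_concentration(100, recovery_fraction = 0.883,
#'                            blubber_mass = 0.1)
adjust_assay_concentration <- function(raw_concentration, buffer_volume = 0.5,
                                       dilution_factor = 1,
                                       recovery_fraction = 1, blubber_mass) {
  if (any(raw_concentration < 0, na.rm = TRUE)) {
    stop("`raw_concentration` must be non-negative", call. = FALSE)
  }
  if (any(buffer_volume <= 0)) stop("`buffer_volume` must be positive",
                                    call. = FALSE)
  if (any(dilution_factor < 1)) stop("`dilution_factor` must be >= 1",
                                     call. = FALSE)
  if (any(recovery_fraction <= 0) || any(recovery_fraction > 1)) {
    stop("`recovery_fraction` must lie in (0, 1]", call. = FALSE)
  }
  if (any(blubber_mass <= 0)) stop("`blubber_mass` must be positive",
                                   call. = FALSE)
  (raw_concentration * buffer_volume * dilution_factor / 1000) /
    (recovery_fraction * blubber_mass)
}

#' Convert a per-tissue concentration to per-lipid
#'
#' Progesterone partitions into the lipid phase, so concentrations can be
#' expressed per gram of extracted lipid rather than per gram of wet tissue:
#' `bp_lipid = bp_tissue / lipid_fraction`. Since lipid fractions are at most
#' 1, the per-lipid value is always at least the per-tissue value.
#'
#' @param bp_tissue Concentration, ng per g of tissue (vectorised).
#' @param lipid_fraction Lipid mass fraction of the sample, in (0, 1].
#' @return Concentration in ng per g of lipid.
#' @export
#' @examples
#' tissue_to_lipid(100, 0.25) # 400 ng/g lipid
tissue_to_lipid <- function(bp_tissue, lipid_fraction) {
  if (any(lipid_fraction <= 0, na.rm = TRUE) ||
      any(lipid_fraction > 1, na.rm = TRUE)) {
    stop("`lipid_fraction` must lie in (0, 1]; division by a non-positive ",
         "fraction is blocked", call. = FALSE)
  }
  bp_tissue / lipid_fraction
}

#' Impute missing lipid fractions
#'
#' Fills missing `lipid_fraction` values with a program-level fallback and
#' flags the imputed rows in `lipid_imputed`. The canonical fallback for
#' necropsy carcasses is 0.664, the mean lipid fraction of the 18 carcass
#' samples with measured lipid content, applied to carcasses whose lipid
#' content was not measured.
#'
#' @param samples Sample table with at least a `lipid_fraction` column.
#' @param fallback Fraction in (0, 1] used for missing values (default
#'   0.664).
#' @return The table with `lipid_fraction` filled and `lipid_imputed` set;
#'   present values are untouched.
#' @export
impute_lipid_fraction <- function(samples, fallback = 0.664) {
  stopifnot(is.data.frame(samples), "lipid_fraction" %in% names(samples))
  stop_if_not_scalar_number(fallback, "fallback")
  if (fallback <= 0 || fallback > 1) {
    stop("`fallback` must lie in (0, 1]", call. = FALSE)
  }
  if (!"lipid_imputed" %in% names(samples)) {
    samples$lipid_imputed <- rep(FALSE, nrow(samples))
  }
  missing <- is.na(samples$lipid_fraction)
  samples$lipid_fraction[missing] <- fallback
  samples$lipid_imputed[missing] <- TRUE
  samples
}

#' Exclude low-lipid samples
#'
#' Very low lipid content makes per-lipid concentrations unstable and drives
#' assignment switching between reporting units, so samples at or below a
#' lipid-fraction cutoff are excluded (boundary inclusive: `lipid <= cutoff`
#' is excluded, matching the "<= 5%" exclusion rule). Rows with missing lipid
#' fraction are retained. The partition is exhaustive and disjoint.
#'
#' @param samples Sample table with a `lipid_fraction` column.
#' @param min_fraction Cutoff in \[0, 1) (default 0.05).
#' @return A list with components `retained` and `excluded`.
#' @export
filter_low_lipid <- function(samples, min_fraction = 0.05) {
  stopifnot(is.data.frame(samples), "lipid_fraction" %in% names(samples))
  stop_if_not_scalar_number(min_fraction, "min_fraction")
  if (min_fraction < 0 || min_fraction >= 1) {
    stop("`min_fraction` must lie in [0, 1)", call. = FALSE)
  }
  low <- !is.na(samples$lipid_fraction) &
    samples$lipid_fraction <= min_fraction
  list(retained = samples[!low, , drop = FALSE],
       excluded = samples[low, , drop = FALSE])
}

#' Natural log of blubber progesterone values
#'
#' All modelling in this package runs on natural-log concentrations (e.g. a
#' 55 ng/g sample is 4.0 on the log scale). Non-positive values are rejected
#' rather than silently floored; apply [floor_detection_limit()] upstream if
#' values at or below the assay detection limit are present.
#'
#' @param values Concentrations, ng per g (all > 0).
#' @return Elementwise natural logarithm.
#' @export
#' @examples
#' log_bp(c(1, 55, 100))
log_bp <- function(values) {
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("all BP values must be positive and finite; floor values at the ",
         "assay detection limit first (see floor_detection_limit())",
         call. = FALSE)
  }
  log(values)
}

#' Floor concentrations at a detection limit
#'
#' Replaces values below `limit` with `limit`, so that the log transform is
#' defined. The default 0.1 ng per g of tissue is the smallest concentration
#' observed in the carcass validation groups.
#'
#' @param values Concentrations, ng per g.
#' @param limit Detection limit (> 0; default 0.1).
#' @return `pmax(values, limit)`.
#' @export
floor_detection_limit <- function(values, limit = 0.1) {
  stop_if_not_scalar_number(limit, "limit")
  if (limit <= 0) stop("`limit` must be positive", call. = FALSE)
  pmax(values, limit)
}
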