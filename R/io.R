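valid_programs <- function() {
  c("SLE_carcass", "NUN_carcass", "SLE_biopsy", "virtual_biopsy")
}
valid_statuses <- function() {
  c("immature_male", "mature_male", "immature_female", "resting", "pregnant",
    "recent_parturition", "lactating", "unknown")
}
valid_colours <- function() c("grey", "off_white", "white")

validate_samples <- function(samples, where = "samples") {
  required <- setdiff(sample_columns(), "latent_truth")
  missing <- setdiff(required, names(samples))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", where,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!"latent_truth" %in% names(samples)) {
    samples$latent_truth <- NA_character_
  }
  samples$lipid_imputed <- isTRUE_vec(samples$lipid_imputed)
  samples$is_virtual <- isTRUE_vec(samples$is_virtual)
  row_error <- function(bad, what) {
    if (any(bad)) {
      stop(sprintf("%s: %s in row(s) %s", where, what,
                   paste(utils::head(which(bad), 10), collapse = ", ")),
           call. = FALSE)
    }
  }
  dup <- duplicated(samples$sample_id)
  row_error(dup, "duplicate sample_id")
  row_error(!is.na(samples$program) & !samples$program %in% valid_programs(),
            "unknown program")
  row_error(!is.na(samples$status) & !samples$status %in% valid_statuses(),
            "unknown status")
  row_error(!is.na(samples$colour_class) &
              !samples$colour_class %in% valid_colours(),
            "unknown colour_class")
  row_error(!is.na(samples$sex) & !samples$sex %in% c("female", "male"),
            "unknown sex")
  row_error(!is.na(samples$bp_tissue_ng_g) & samples$bp_tissue_ng_g < 0,
            "negative bp_tissue_ng_g")
  row_error(!is.na(samples$bp_lipid_ng_g) & samples$bp_lipid_ng_g < 0,
            "negative bp_lipid_ng_g")
  row_error(!is.na(samples$lipid_fraction) &
              (samples$lipid_fraction <= 0 | samples$lipid_fraction > 1),
            "lipid_fraction outside (0, 1]")
  samples[sample_columns()]
}

#' Read a sample table from CSV
#'
#' Reads the canonical sample schema (`sample_id`, `program`, `sex`,
#' `colour_class`, `status`, `bp_tissue_ng_g`, `bp_lipid_ng_g`,
#' `lipid_fraction`, `lipid_imputed`, `is_virtual`, `latent_truth`), UTF-8
#' with a mandatory header and empty fields for missing values. Unknown enum
#' values, duplicate ids and negative concentrations are reported with row
#' numbers. `read_samples(write_samples(x, p))` reproduces `x` exactly.
#'
#' @param path Path to a CSV file.
#' @return A validated sample `data.frame`.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  classes <- c(sample_id = "character", program = "character",
               sex = "character", colour_class = "character",
               status = "character", bp_tissue_ng_g = "numeric",
               bp_lipid_ng_g = "numeric", lipid_fraction = "numeric",
               lipid_imputed = "logical", is_virtual = "logical",
               latent_truth = "character")
  raw <- read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                  colClasses = NA, fileEncoding = "UTF-8")
  for (col in intersect(names(classes), names(raw))) {
    raw[[col]] <- switch(classes[[col]],
                         character = as.character(raw[[col]]),
                         numeric = as.numeric(raw[[col]]),
                         logical = as.logical(raw[[col]]))
  }
  out <- validate_samples(raw, where = path)
  rownames(out) <- NULL
  out
}

#' Write a sample table to CSV
#'
#' @param samples A sample table in the canonical schema (validated before
#'   writing; the input is never mutated).
#' @param path Output path.
#' @return `path`, invisibly.
#' @rdname read_samples
#' @export
write_samples <- function(samples, path) {
  out <- validate_samples(samples, where = "write_samples")
  # 17 significant digits round-trip doubles exactly through the CSV
  for (col in c("bp_tissue_ng_g", "bp_lipid_ng_g", "lipid_fraction")) {
    out[[col]] <- ifelse(is.na(out[[col]]), NA_character_,
                         sprintf("%.17g", out[[col]]))
  }
  write.csv(out, path, row.names = FALSE, na = "", fileEncoding = "UTF-8",
            quote = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles every tunable of [run_pipeline()]: which classification approaches
#' to run, which reporting units, the fixed thresholds (100 ng/g tissue, 150
#' ng/g lipid), the low-lipid exclusion cutoff (5%), the carcass lipid
#' fallback (66.4%), MCMC settings, the mixture K search space, the maturity
#' schedule, the probability cutoff and the run seed. Every stochastic stage
#' derives its own sub-seed from `seed`.
#'
#' @param approaches Subset of `c("threshold", "mixture", "logistic")`.
#' @param units Subset of `c("tissue", "lipid")`.
#' @param threshold_tissue,threshold_lipid Fixed thresholds per unit.
#' @param lipid_exclusion Low-lipid cutoff in \[0, 1) (set `NULL` to skip).
#' @param lipid_fallback Imputation fallback for missing lipid fractions.
#' @param mcmc An [mcmc_settings()] object (its seed is overridden by a
#'   sub-seed of `seed`).
#' @param k_range Mixture component search space.
#' @param schedule A [maturity_schedule()].
#' @param cutoff Probability cutoff for the logistic labels.
#' @param seed Run seed.
#' @param outdir Optional output directory; when set, [run_pipeline()] writes
#'   classification CSVs and a plain-text run manifest there.
#' @return An object of class `run_config`.
#' @export
run_config <- function(approaches = c("threshold", "mixture", "logistic"),
                       units = "tissue", threshold_tissue = 100,
                       threshold_lipid = 150, lipid_exclusion = 0.05,
                       lipid_fallback = 0.664, mcmc = scaled_mcmc_settings(),
                       k_range = 1:3, schedule = maturity_schedule(),
                       cutoff = 0.5, seed = 1L, outdir = NULL) {
  approaches <- match.arg(approaches,
                          c("threshold", "mixture", "logistic"),
                          several.ok = TRUE)
  units <- match.arg(units, c("tissue", "lipid"), several.ok = TRUE)
  stopifnot(inherits(mcmc, "mcmc_settings"),
            inherits(schedule, "maturity_schedule"))
  structure(
    list(approaches = approaches, units = units,
         threshold_tissue = threshold_tissue,
         threshold_lipid = threshold_lipid,
         lipid_exclusion = lipid_exclusion, lipid_fallback = lipid_fallback,
         mcmc = mcmc, k_range = k_range, schedule = schedule,
         cutoff = cutoff, seed = as.integer(seed), outdir = outdir),
    class = "run_config"
  )
}

bp_column <- function(unit) {
  if (unit == "tissue") "bp_tissue_ng_g" else "bp_lipid_ng_g"
}

#' Run the classification pipeline end to end
#'
#' Preprocesses a sample table (lipid imputation for rows with missing lipid
#' fraction, per-lipid concentrations, low-lipid exclusion), runs the
#' requested classification approaches on the requested reporting units,
#' scores known-status rows against [expected_label()], and — when colour
#' classes are present — estimates the maturity-adjusted pregnancy rate from
#' the mixture labels (falling back to any available approach). Virtual
#' biopsies carry no BP value and are skipped by the classifiers but counted
#' as mature non-pregnant females in the rate. With `outdir` set, writes the
#' classified table, the excluded rows and a reproducible plain-text manifest
#' (no timestamps, so identical runs are byte-identical).
#'
#' @param samples A sample table (canonical schema) or a path to one.
#' @param config A [run_config()].
#' @return List with elements `samples` (classified table, one label column
#'   per approach/unit), `excluded`, `fits`, `evaluation`, `rate` and
#'   `manifest`.
#' @export
run_pipeline <- function(samples, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(samples)) samples <- read_samples(samples)
  samples <- validate_samples(samples)

  n_missing_lipid <- sum(is.na(samples$lipid_fraction) & !samples$is_virtual)
  if ("lipid" %in% config$units) {
    samples <- impute_lipid_fraction(samples, fallback = config$lipid_fallback)
    recompute <- is.na(samples$bp_lipid_ng_g) &
      !is.na(samples$bp_tissue_ng_g) & !is.na(samples$lipid_fraction)
    samples$bp_lipid_ng_g[recompute] <-
      tissue_to_lipid(samples$bp_tissue_ng_g[recompute],
                      samples$lipid_fraction[recompute])
  }
  excluded <- empty_samples()
  if (!is.null(config$lipid_exclusion)) {
    parts <- filter_low_lipid(samples, config$lipid_exclusion)
    samples <- parts$retained
    excluded <- parts$excluded
  }

  stage_seeds <- split_seed(config$seed, 4L)
  fits <- list()
  evaluation <- list()
  known <- !is.na(samples$status) & samples$status != "unknown" &
    !samples$is_virtual

  for (unit in config$units) {
    bp <- samples[[bp_column(unit)]]
    usable <- !is.na(bp) & !samples$is_virtual

    if ("threshold" %in% config$approaches) {
      thr <- if (unit == "tissue") config$threshold_tissue else
        config$threshold_lipid
      rule <- threshold_rule(thr, unit = unit)
      col <- paste0("label_threshold_", unit)
      samples[[col]] <- NA_character_
      samples[[col]][usable] <- classify_fixed_threshold(bp[usable], rule)
    }

    if ("mixture" %in% config$approaches) {
      mcmc <- config$mcmc
      mcmc$seed <- as.integer(stage_seeds[1])
      sel <- select_mixture_k(log_bp(bp[usable]), k_range = config$k_range,
                              settings = mcmc)
      fits[[paste0("mixture_", unit)]] <- sel
      memb <- posterior_membership(sel$best_fit, bp[usable])
      col <- paste0("label_mixture_", unit)
      samples[[col]] <- NA_character_
      samples[[col]][usable] <- colnames(memb)[max.col(memb, "first")]
    }

    if ("logistic" %in% config$approaches) {
      mcmc <- config$mcmc
      mcmc$seed <- as.integer(stage_seeds[2])
      resp <- rep(NA_integer_, nrow(samples))
      resp[known] <- logistic_response(samples$status[known])
      fit <- fit_logistic(log_bp(bp[usable]), resp[usable], settings = mcmc)
      fits[[paste0("logistic_", unit)]] <- fit
      # every individual (trained on or predicted) is labelled by its
      # posterior mean probability, so known-status rows can be misclassified
      prob <- vapply(log_bp(bp[usable]), function(x) {
        mean(plogis(fit$beta0 + fit$beta1 * x))
      }, numeric(1))
      col <- paste0("label_logistic_", unit)
      samples[[col]] <- NA_character_
      samples[[col]][usable] <- classify_by_probability(prob, config$cutoff)
    }

    if (any(known)) {
      for (appr in config$approaches) {
        col <- paste0("label_", appr, "_", unit)
        rows <- known & !is.na(samples[[col]])
        if (!any(rows)) next
        evaluation[[paste0(appr, "_", unit)]] <- misclassification_count(
          samples[[col]][rows], expected_label(samples$status[rows]),
          status = samples$status[rows])
      }
    }
  }

  rate <- NULL
  rate_approach <- intersect(c("mixture", "threshold", "logistic"),
                             config$approaches)[1]
  rate_col <- paste0("label_", rate_approach, "_", config$units[1])
  unknown_rows <- !known
  if (!is.na(rate_approach) && any(unknown_rows) &&
      any(!is.na(samples$colour_class[unknown_rows]))) {
    sub <- samples[unknown_rows, , drop = FALSE]
    rate <- pregnancy_rate_from_labels(sub, sub[[rate_col]],
                                       schedule = config$schedule)
  }

  manifest <- c(
    sprintf("package_version: %s",
            as.character(utils::packageVersion("belugapreg"))),
    sprintf("seed: %d", config$seed),
    sprintf("approaches: %s", paste(config$approaches, collapse = ",")),
    sprintf("units: %s", paste(config$units, collapse = ",")),
    sprintf("threshold_tissue: %g", config$threshold_tissue),
    sprintf("threshold_lipid: %g", config$threshold_lipid),
    sprintf("lipid_exclusion: %s",
            if (is.null(config$lipid_exclusion)) "none" else
              sprintf("%g", config$lipid_exclusion)),
    sprintf("mcmc: %d iterations, %d chains, thin %d, burn-in %d",
            config$mcmc$n_iterations, config$mcmc$n_chains, config$mcmc$thin,
            config$mcmc$burn_in),
    sprintf("n_samples: %d", nrow(samples)),
    sprintf("n_excluded_low_lipid: %d", nrow(excluded)),
    sprintf("n_lipid_imputed: %d",
            if ("lipid" %in% config$units) n_missing_lipid else 0L)
  )

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    keep <- samples
    keep$latent_truth <- NA_character_  # truth never leaves the run bundle
    utils::write.csv(keep, file.path(config$outdir, "classifications.csv"),
                     row.names = FALSE, na = "")
    if (nrow(excluded)) {
      write_samples(excluded, file.path(config$outdir, "excluded.csv"))
    }
    writeLines(manifest, file.path(config$outdir, "manifest.txt"))
  }

  list(samples = samples, excluded = excluded, fits = fits,
       evaluation = evaluation, rate = rate, manifest = manifest)
}
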