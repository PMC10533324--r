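#' Construct a logistic-fit object from posterior draws
#'
#' Low-level constructor used by [fit_logistic()]; also handy for building
#' degenerate (point-mass) fits in tests. `beta0` and `beta1` are posterior
#' draws of the intercept and the slope per unit of natural-log BP.
#'
#' @param beta0,beta1 Numeric draw vectors of equal length.
#' @param chain Optional chain index per draw.
#' @param rhat,settings,predicted Optional diagnostics and predictions
#'   attached by [fit_logistic()].
#' @return An object of class `logistic_fit` with an `odds_ratio` summary
#'   (posterior mean and 95% credible interval of `exp(beta1)`).
#' @export
logistic_fit <- function(beta0, beta1, chain = NULL, rhat = NULL,
                         settings = NULL, predicted = NULL) {
  stopifnot(is.numeric(beta0), is.numeric(beta1),
            length(beta0) == length(beta1), length(beta0) >= 1)
  or_draws <- exp(beta1)
  structure(
    list(beta0 = beta0, beta1 = beta1, chain = chain, rhat = rhat,
         settings = settings, predicted = predicted,
         odds_ratio = c(mean = mean(or_draws),
                        lower = unname(quantile(or_draws, 0.025)),
                        upper = unname(quantile(or_draws, 0.975)))),
    class = "logistic_fit"
  )
}

#' Map reproductive statuses to the logistic response coding
#'
#' Pregnant females are the positive class (1); males, immature females,
#' resting and lactating females are the negative class (0). Recently
#' parturient females, whose blubber progesterone may still reflect the ended
#' pregnancy, are coded `NA`: they are excluded from the training likelihood
#' and predicted as missing responses instead. `"unknown"` is likewise `NA`.
#'
#' @param status Character vector of reproductive statuses.
#' @return Integer vector of 1, 0 and `NA`.
#' @export
#' @examples
#' logistic_response(c("pregnant", "lactating", "recent_parturition"))
logistic_response <- function(status) {
  out <- rep(NA_integer_, length(status))
  out[status == "pregnant"] <- 1L
  out[status %in% c("immature_male", "mature_male", "immature_female",
                    "resting", "lactating")] <- 0L
  unknown <- !status %in% c("pregnant", "recent_parturition", "unknown",
                            "immature_male", "mature_male", "immature_female",
                            "resting", "lactating") & !is.na(status)
  if (any(unknown)) {
    stop("unrecognised status value(s): ",
         paste(unique(status[unknown]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Bayesian logistic regression of pregnancy on log BP
#'
#' Fits `pregnant ~ log BP` with a logit link by random-walk Metropolis,
#' under weakly informative Normal(0, 10) priors on both coefficients.
#' Observations with `NA` response are treated as missing responses: they
#' contribute nothing to the likelihood, and each receives a posterior
#' predictive probability of pregnancy (the draw-averaged
#' `plogis(beta0 + beta1 * x)`). The sampler runs on the centred predictor
#' for mixing and reports coefficients on the original scale. Convergence is
#' summarised by Gelman-Rubin R-hat on both coefficients (warning above 1.1).
#'
#' @param log_bp Natural-log BP values for all individuals (training and
#'   to-predict).
#' @param pregnant Response vector aligned with `log_bp`: 1/TRUE pregnant,
#'   0/FALSE non-pregnant, `NA` to predict. Both classes must be present
#'   among the non-missing responses.
#' @param settings An [mcmc_settings()] object.
#' @param prior_sd Prior SD for both coefficients (default 10).
#' @param prop_sd Length-2 random-walk proposal SDs for (intercept, slope) on
#'   the centred scale.
#' @return A [logistic_fit()] whose `predicted` element is a data frame of
#'   the `NA`-response rows (`index`, `log_bp`, `probability`).
#' @export
#' @examples
#' \donttest{
#' x <- c(rnorm(30, 1, 1), rnorm(30, 6, 1))
#' y <- rep(c(0, 1), each = 30)
#' fit <- fit_logistic(x, y, settings = scaled_mcmc_settings(seed = 1))
#' fit$odds_ratio
#' }
fit_logistic <- function(log_bp, pregnant, settings = mcmc_settings(),
                         prior_sd = 10, prop_sd = c(0.8, 0.8)) {
  stopifnot(inherits(settings, "mcmc_settings"),
            length(log_bp) == length(pregnant))
  if (any(!is.finite(log_bp))) stop("`log_bp` must be finite", call. = FALSE)
  y <- as.integer(pregnant)
  if (any(!y %in% c(0L, 1L) & !is.na(y))) {
    stop("`pregnant` must be 0/1/NA", call. = FALSE)
  }
  obs <- !is.na(y)
  if (sum(y[obs] == 1) == 0 || sum(y[obs] == 0) == 0) {
    stop("training data must contain both pregnant and non-pregnant ",
         "individuals", call. = FALSE)
  }
  x_obs <- log_bp[obs]
  y_obs <- y[obs]
  if (max(x_obs[y_obs == 0]) < min(x_obs[y_obs == 1])) {
    warning("classes are completely separated on log BP; the posterior is ",
            "driven by the priors at large slopes", call. = FALSE)
  }
  xbar <- mean(x_obs)

  chain_seeds <- split_seed(settings$seed, settings$n_chains)
  per_chain <- vector("list", settings$n_chains)
  for (ch in seq_len(settings$n_chains)) {
    per_chain[[ch]] <- with_seed(chain_seeds[ch], logistic_mh_cpp(
      x_obs - xbar, y_obs, settings$n_iterations, settings$burn_in,
      settings$thin, prior_sd, prop_sd[1], prop_sd[2]))
  }
  a0 <- unlist(lapply(per_chain, `[[`, "b0"))
  a1 <- unlist(lapply(per_chain, `[[`, "b1"))
  beta1 <- a1
  beta0 <- a0 - a1 * xbar
  chain <- rep(seq_len(settings$n_chains), each = settings$draws_per_chain)

  rhat <- NULL
  if (settings$n_chains >= 2) {
    m0 <- vapply(per_chain, function(pc) pc$b0 - pc$b1 * xbar,
                 numeric(settings$draws_per_chain))
    m1 <- vapply(per_chain, `[[`, numeric(settings$draws_per_chain), "b1")
    rhat <- c(beta0 = gelman_rubin(m0), beta1 = gelman_rubin(m1))
    if (any(rhat > 1.1)) {
      warning(sprintf("possible non-convergence: max R-hat %.3f", max(rhat)),
              call. = FALSE)
    }
  }

  predicted <- NULL
  if (any(!obs)) {
    idx <- which(!obs)
    prob <- vapply(idx, function(i) {
      mean(plogis(beta0 + beta1 * log_bp[i]))
    }, numeric(1))
    predicted <- data.frame(index = idx, log_bp = log_bp[idx],
                            probability = prob)
  }
  logistic_fit(beta0, beta1, chain = chain, rhat = rhat, settings = settings,
               predicted = predicted)
}

#' Dichotomise pregnancy probabilities
#'
#' A mean posterior probability at or above the cutoff indicates pregnancy;
#' below it, non-pregnancy. The canonical cutoff is 0.5 and the boundary is
#' inclusive (a probability of exactly 0.5 is called pregnant).
#'
#' @param probabilities Probabilities in \[0, 1\].
#' @param cutoff Scalar strictly inside (0, 1); default 0.5.
#' @return Character labels, `"pregnant"` or `"non_pregnant"`.
#' @export
#' @examples
#' classify_by_probability(c(0.49, 0.50, 1.0))
classify_by_probability <- function(probabilities, cutoff = 0.5) {
  stop_if_not_scalar_number(cutoff, "cutoff")
  if (cutoff <= 0 || cutoff >= 1) {
    stop("`cutoff` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (any(probabilities < 0, na.rm = TRUE) ||
      any(probabilities > 1, na.rm = TRUE)) {
    stop("`probabilities` must lie in [0, 1]", call. = FALSE)
  }
  ifelse(probabilities >= cutoff, "pregnant", "non_pregnant")
}

#' Equal-odds concentration of a logistic fit
#'
#' The concentration at which the model returns probability 0.5, computed
#' per draw as `exp(-beta0 / beta1)` (the predictor is natural-log BP) and
#' summarised by the posterior mean and 95% credible interval. Defined only
#' when the slope draws are bounded away from zero; if they straddle zero the
#' ratio is unstable and an error recommends reporting the interval on the
#' log scale instead.
#'
#' @param fit A [logistic_fit()].
#' @return List with `mean`, `lower`, `upper` (ng per g) and the per-draw
#'   vector `draws`.
#' @export
#' @examples
#' equal_odds_point(logistic_fit(beta0 = -4.6052, beta1 = 1))$mean # ~ 100
equal_odds_point <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  b1 <- fit$beta1
  if (any(b1 <= 0) && any(b1 >= 0)) {
    stop("slope draws straddle 0: the equal-odds concentration is not ",
         "identified; report the interval on the log scale instead",
         call. = FALSE)
  }
  draws <- exp(-fit$beta0 / b1)
  list(mean = mean(draws),
       lower = unname(quantile(draws, 0.025)),
       upper = unname(quantile(draws, 0.975)),
       draws = draws)
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Bayesian logistic fit: %d draws\n", length(x$beta0)))
  cat(sprintf("  intercept: %.2f [%.2f, %.2f]\n", mean(x$beta0),
              quantile(x$beta0, 0.025), quantile(x$beta0, 0.975)))
  cat(sprintf("  slope (per unit log BP): %.2f [%.2f, %.2f]\n", mean(x$beta1),
              quantile(x$beta1, 0.025), quantile(x$beta1, 0.975)))
  cat(sprintf("  odds ratio: %.2f [%.2f, %.2f]\n", x$odds_ratio["mean"],
              x$odds_ratio["lower"], x$odds_ratio["upper"]))
  if (!is.null(x$rhat)) cat(sprintf("  max R-hat: %.3f\n", max(x$rhat)))
  if (!is.null(x$predicted)) {
    cat(sprintf("  predicted missing responses: %d\n", nrow(x$predicted)))
  }
  invisible(x)
}
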