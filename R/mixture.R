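#' MCMC sampler settings
#'
#' Defaults mirror the analysis protocol for the BP models: 50 000 iterations
#' of three independent chains with a burn-in of 10 000 and thinning of 40,
#' which retains 1000 draws per chain. `(n_iterations - burn_in) / thin` must
#' be a positive integer.
#'
#' @param n_iterations Total iterations per chain.
#' @param n_chains Number of independent chains (>= 1).
#' @param thin Thinning interval.
#' @param burn_in Discarded initial iterations.
#' @param seed Integer seed; each chain draws through its own sub-seed.
#' @return An object of class `mcmc_settings`.
#' @seealso [scaled_mcmc_settings()] for a fast configuration suited to
#'   simulation studies and tests.
#' @export
mcmc_settings <- function(n_iterations = 50000L, n_chains = 3L, thin = 40L,
                          burn_in = 10000L, seed = 1L) {
  for (nm in c("n_iterations", "n_chains", "thin", "burn_in", "seed")) {
    stop_if_not_scalar_number(get(nm), nm)
  }
  if (n_chains < 1) stop("`n_chains` must be >= 1", call. = FALSE)
  if (burn_in < 0 || thin < 1) {
    stop("`burn_in` must be >= 0 and `thin` >= 1", call. = FALSE)
  }
  kept <- (n_iterations - burn_in) / thin
  if (kept <= 0 || kept != round(kept)) {
    stop("(n_iterations - burn_in) / thin must be a positive integer; ",
         sprintf("got %.3f", kept), call. = FALSE)
  }
  structure(
    list(n_iterations = as.integer(n_iterations),
         n_chains = as.integer(n_chains), thin = as.integer(thin),
         burn_in = as.integer(burn_in), seed = as.integer(seed),
         draws_per_chain = as.integer(kept)),
    class = "mcmc_settings"
  )
}

#' Scaled-down MCMC settings for simulation studies
#'
#' 5000 iterations, burn-in 1000, thinning 4, three chains — the same 1000
#' retained draws per chain as the full protocol at a fraction of the cost.
#' Used by the test suite and recovery simulations; the full settings remain
#' the package default.
#'
#' @param seed Integer seed.
#' @return An `mcmc_settings` object.
#' @export
scaled_mcmc_settings <- function(seed = 1L) {
  mcmc_settings(n_iterations = 5000L, n_chains = 3L, thin = 4L,
                burn_in = 1000L, seed = seed)
}

#' Construct a mixture-fit object from posterior draws
#'
#' Low-level constructor, used by [fit_mixture()] and useful for building
#' degenerate fits (e.g. point-mass draws) in tests and examples. Draw
#' matrices have one row per retained draw and one column per component;
#' every row of `mu` must be ascending (the identifiability constraint) and
#' every row of `w` must sum to 1.
#'
#' @param mu,sigma,w Draw matrices (draws x K) of component means, SDs and
#'   weights on the natural-log scale.
#' @param chain Optional integer vector mapping each draw to its chain.
#' @param log_values Optional data vector the fit was conditioned on.
#' @param waic,rhat,settings Optional diagnostics attached by [fit_mixture()].
#' @return An object of class `mixture_fit` with elements `k`, `mu`, `sigma`,
#'   `w`, `pregnant_cluster` (index of the highest-mean component), and any
#'   supplied diagnostics.
#' @export
mixture_fit <- function(mu, sigma, w, chain = NULL, log_values = NULL,
                        waic = NULL, rhat = NULL, settings = NULL) {
  mu <- as.matrix(mu); sigma <- as.matrix(sigma); w <- as.matrix(w)
  k <- ncol(mu)
  stopifnot(k >= 1, all(dim(mu) == dim(sigma)), all(dim(mu) == dim(w)))
  if (any(sigma <= 0)) stop("all sigma draws must be positive", call. = FALSE)
  if (k > 1 && any(mu[, -1, drop = FALSE] < mu[, -k, drop = FALSE])) {
    stop("every draw of `mu` must be in ascending component order",
         call. = FALSE)
  }
  if (any(abs(rowSums(w) - 1) > 1e-8) || any(w < 0)) {
    stop("every draw of `w` must be non-negative and sum to 1", call. = FALSE)
  }
  structure(
    list(k = k, mu = mu, sigma = sigma, w = w, chain = chain,
         log_values = log_values, waic = waic, rhat = rhat,
         settings = settings, pregnant_cluster = k),
    class = "mixture_fit"
  )
}

#' Fit a Bayesian Gaussian mixture to log BP values
#'
#' Fits a K-component normal mixture to natural-log blubber progesterone by
#' Gibbs sampling, with weakly informative priors: component means
#' Normal(0, 10) on the log scale (covering the plausible log-BP range of
#' about -2.3 to 7.1 without favouring clusters), component SDs
#' Half-Normal(5), and symmetric Dirichlet(1) weights. Label switching is
#' suppressed by restoring ascending-mean order at every sweep, so the
#' constraint holds in every retained draw. Convergence is summarised by the
#' Gelman-Rubin statistic for every component mean, SD and weight; any value
#' above 1.1 triggers a warning (never silent success).
#'
#' @param log_values Natural-log BP values (finite; length > `k`).
#' @param k Number of components (>= 1).
#' @param settings An [mcmc_settings()] object.
#' @param prior_mu_sd,prior_sigma_sd,dirichlet_alpha Prior hyperparameters.
#' @param prop_sd_log_sigma Random-walk proposal SD for the log-sigma
#'   Metropolis step.
#' @return A [mixture_fit()] with draws pooled across chains, the chain index
#'   of each draw, per-parameter `rhat`, and the fit's WAIC.
#' @export
#' @examples
#' \donttest{
#' x <- log_bp(simulate_known_samples(list(
#'   group_spec("resting", 100, 3.1, 4.5),
#'   group_spec("pregnant", 100, 365, 244)), seed = 1)$bp_tissue_ng_g)
#' fit <- fit_mixture(x, k = 2, settings = scaled_mcmc_settings(seed = 1))
#' fit
#' }
fit_mixture <- function(log_values, k, settings = mcmc_settings(),
                        prior_mu_sd = 10, prior_sigma_sd = 5,
                        dirichlet_alpha = 1, prop_sd_log_sigma = 0.25) {
  stopifnot(inherits(settings, "mcmc_settings"))
  if (any(!is.finite(log_values))) {
    stop("`log_values` must all be finite", call. = FALSE)
  }
  stop_if_not_scalar_number(k, "k")
  if (k < 1 || k != round(k)) stop("`k` must be a positive integer",
                                   call. = FALSE)
  if (length(log_values) <= k) {
    stop("need more observations than mixture components", call. = FALSE)
  }
  k <- as.integer(k)

  chain_seeds <- split_seed(settings$seed, settings$n_chains)
  per_chain <- vector("list", settings$n_chains)
  for (ch in seq_len(settings$n_chains)) {
    per_chain[[ch]] <- with_seed(chain_seeds[ch], mixture_gibbs_cpp(
      as.numeric(log_values), k, settings$n_iterations, settings$burn_in,
      settings$thin, prior_mu_sd, prior_sigma_sd, dirichlet_alpha,
      prop_sd_log_sigma))
  }
  mu <- do.call(rbind, lapply(per_chain, `[[`, "mu"))
  sigma <- do.call(rbind, lapply(per_chain, `[[`, "sigma"))
  w <- do.call(rbind, lapply(per_chain, `[[`, "w"))
  chain <- rep(seq_len(settings$n_chains), each = settings$draws_per_chain)

  rhat <- numeric(0)
  if (settings$n_chains >= 2) {
    per_param <- function(draws, prefix) {
      out <- numeric(k)
      for (j in seq_len(k)) {
        m <- vapply(per_chain, function(pc) pc[[draws]][, j],
                    numeric(settings$draws_per_chain))
        out[j] <- gelman_rubin(m)
      }
      names(out) <- paste0(prefix, seq_len(k))
      out
    }
    rhat <- c(per_param("mu", "mu"), per_param("sigma", "sigma"),
              per_param("w", "w"))
  }

  fit <- mixture_fit(mu, sigma, w, chain = chain,
                     log_values = as.numeric(log_values), rhat = rhat,
                     settings = settings)
  fit$waic <- compute_waic(fit)
  if (length(rhat) && any(rhat > 1.1)) {
    bad <- names(rhat)[rhat > 1.1]
    warning(sprintf(
      "possible non-convergence: R-hat > 1.1 for %s (max %.3f)",
      paste(bad, collapse = ", "), max(rhat)), call. = FALSE)
  }
  fit
}

# Pointwise mixture density for every retained draw: S x n matrix.
pointwise_density <- function(fit, log_values) {
  s <- nrow(fit$mu)
  n <- length(log_values)
  x <- matrix(log_values, s, n, byrow = TRUE)
  dens <- matrix(0, s, n)
  for (j in seq_len(fit$k)) {
    dens <- dens + fit$w[, j] * dnorm(x, mean = fit$mu[, j],
                                      sd = fit$sigma[, j])
  }
  dens
}

#' Widely applicable information criterion of a mixture fit
#'
#' `WAIC = -2 * (lppd - p_waic)` where `lppd` is the log pointwise predictive
#' density (log of the posterior-mean density at each observation, summed)
#' and `p_waic` is the effective number of parameters in its variance form
#' (the summed posterior variance of the pointwise log densities). Lower is
#' better; WAIC guides the choice of the number of clusters.
#'
#' @param fit A [mixture_fit()].
#' @param log_values Data to evaluate; defaults to the data the fit was
#'   conditioned on. Supplying data of a different length than the fit's is
#'   an error (draw/data mismatch).
#' @return WAIC (scalar, deviance scale).
#' @export
compute_waic <- function(fit, log_values = NULL) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (is.null(log_values)) log_values <- fit$log_values
  if (is.null(log_values) || length(log_values) == 0) {
    stop("no data supplied and the fit carries none", call. = FALSE)
  }
  if (!is.null(fit$log_values) &&
      length(log_values) != length(fit$log_values)) {
    stop("`log_values` does not match the data the draws condition on",
         call. = FALSE)
  }
  dens <- pointwise_density(fit, log_values)
  lppd <- sum(log(colMeans(dens)))
  p_waic <- sum(apply(log(dens), 2, var))
  -2 * (lppd - p_waic)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic PSRF: with m chains of length n, within-chain variance `W` (mean
#' of the chain variances), between-chain variance `B = n * var(chain
#' means)`, and pooled estimate `V = (n-1)/n * W + B/n`, the statistic is
#' `sqrt(V / W)`. Values near 1 indicate convergence; this package warns at
#' 1.1.
#'
#' @param chains A numeric matrix (iterations x chains, >= 2 chains of equal
#'   length >= 2) or a list of equal-length numeric vectors.
#' @return The R-hat scalar.
#' @export
#' @examples
#' set.seed(1)
#' gelman_rubin(cbind(rnorm(500), rnorm(500)))
gelman_rubin <- function(chains) {
  if (is.list(chains)) {
    len <- lengths(chains)
    if (length(unique(len)) != 1) {
      stop("all chains must have equal length", call. = FALSE)
    }
    chains <- do.call(cbind, chains)
  }
  chains <- as.matrix(chains)
  m <- ncol(chains)
  n <- nrow(chains)
  if (m < 2) stop("at least 2 chains are required", call. = FALSE)
  if (n < 2) stop("chains must have length >= 2", call. = FALSE)
  w <- mean(apply(chains, 2, var))
  b <- n * var(colMeans(chains))
  if (w == 0) return(if (b == 0) 1 else Inf)
  v <- (n - 1) / n * w + b / n
  sqrt(v / w)
}

#' Posterior cluster membership of observations
#'
#' For each raw concentration, the posterior probability of belonging to each
#' mixture component, averaged over the retained draws (for each draw, the
#' responsibilities `w_j * dnorm(x; mu_j, sigma_j)` normalised across
#' components). Rows sum to 1. The hard assignment is the most probable
#' cluster.
#'
#' @param fit A [mixture_fit()].
#' @param values Raw concentrations, ng per g (> 0; logged internally).
#' @return Matrix (observations x components) of membership probabilities,
#'   with component labels from [label_clusters()] as column names.
#' @export
posterior_membership <- function(fit, values) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("`values` must be positive (the log transform is undefined ",
         "otherwise)", call. = FALSE)
  }
  x <- log(values)
  s <- nrow(fit$mu)
  n <- length(x)
  xm <- matrix(x, s, n, byrow = TRUE)
  num <- vector("list", fit$k)
  tot <- matrix(0, s, n)
  for (j in seq_len(fit$k)) {
    num[[j]] <- fit$w[, j] * dnorm(xm, mean = fit$mu[, j], sd = fit$sigma[, j])
    tot <- tot + num[[j]]
  }
  out <- vapply(num, function(nj) colMeans(nj / tot), numeric(n))
  out <- matrix(out, nrow = n, ncol = fit$k)
  colnames(out) <- suppressWarnings(label_clusters(fit))
  out
}

#' Semantic labels for mixture components
#'
#' Components are in ascending order of posterior mean, and the highest-mean
#' component corresponds to pregnant females. With two components the labels
#' are non-pregnant/pregnant; with three, the middle component is the
#' "intermediate" progesterone cluster (lactating and recently parturient
#' females often sit there). A single component is "undifferentiated" (with a
#' warning), since nothing separates pregnant from non-pregnant.
#'
#' @param fit A [mixture_fit()].
#' @return Character vector of length `fit$k`, in component order.
#' @export
label_clusters <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  k <- fit$k
  if (k == 1) {
    warning("a single-component fit cannot separate pregnant from ",
            "non-pregnant; labelling it 'undifferentiated'", call. = FALSE)
    return("undifferentiated")
  }
  if (k == 2) return(c("non_pregnant", "pregnant"))
  if (k == 3) return(c("non_pregnant", "intermediate", "pregnant"))
  c("non_pregnant", paste0("intermediate_", seq_len(k - 2)), "pregnant")
}

#' Choose the number of mixture components by WAIC
#'
#' Fits the mixture for each candidate K and returns the fit with the lowest
#' WAIC. The canonical search space is 1 to 3 clusters.
#'
#' @param log_values Natural-log BP values.
#' @param k_range Candidate component counts (default `1:3`).
#' @param settings An [mcmc_settings()] object; each K fits under the same
#'   settings.
#' @param ... Passed to [fit_mixture()].
#' @return List with `best_k`, `best_fit`, `waic` (named vector over
#'   `k_range`) and `fits` (all fits).
#' @export
select_mixture_k <- function(log_values, k_range = 1:3,
                             settings = mcmc_settings(), ...) {
  stopifnot(length(k_range) >= 1, all(k_range >= 1))
  fits <- lapply(k_range, function(k) {
    fit_mixture(log_values, k = k, settings = settings, ...)
  })
  waic <- vapply(fits, `[[`, numeric(1), "waic")
  names(waic) <- paste0("k", k_range)
  best <- which.min(waic)
  list(best_k = k_range[best], best_fit = fits[[best]], waic = waic,
       fits = fits)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Bayesian Gaussian mixture fit: %d component(s), %d draws\n",
              x$k, nrow(x$mu)))
  summ <- data.frame(
    component = seq_len(x$k),
    label = suppressWarnings(label_clusters(x)),
    mean_log = colMeans(x$mu),
    sd_log = colMeans(x$sigma),
    weight = colMeans(x$w),
    mean_ng_g = exp(colMeans(x$mu))
  )
  print(summ, row.names = FALSE, digits = 3)
  if (!is.null(x$waic)) cat(sprintf("WAIC: %.1f\n", x$waic))
  if (length(x$rhat)) cat(sprintf("max R-hat: %.3f\n", max(x$rhat)))
  invisible(x)
}
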