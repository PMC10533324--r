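test_that("mcmc_settings enforces the draw-count arithmetic", {
  s <- mcmc_settings()
  expect_equal(s$draws_per_chain, 1000L)  # (50000-10000)/40
  expect_equal(scaled_mcmc_settings()$draws_per_chain, 1000L)
  expect_error(mcmc_settings(n_iterations = 1000, burn_in = 999, thin = 40),
               "positive integer")
  expect_error(mcmc_settings(n_iterations = 100, burn_in = 200, thin = 1),
               "positive integer")
})

test_that("a single-component fit collapses to the normal model", {
  x <- two_group_log_bp(seed = 11, n_per_group = 50L)
  fit <- fit_mixture(x, k = 1, settings = scaled_mcmc_settings(seed = 1))
  post_mean <- mean(fit$mu[, 1])
  post_sd <- sd(fit$mu[, 1])
  expect_lt(abs(post_mean - mean(x)), 2 * post_sd)
})

test_that("two-component fits recover the generating log-means", {
  x <- two_group_log_bp(seed = 21)
  fit <- fit_mixture(x, k = 2, settings = scaled_mcmc_settings(seed = 2))
  true_mu <- c(lognormal_params(3.1, 4.5)$meanlog,
               lognormal_params(365, 244)$meanlog)
  for (j in 1:2) {
    expect_lt(abs(mean(fit$mu[, j]) - true_mu[j]), 3 * sd(fit$mu[, j]))
  }
  expect_true(all(fit$rhat < 1.1))
})

test_that("every retained draw satisfies the ascending-means constraint", {
  for (k in 2:3) {
    x <- two_group_log_bp(seed = 30 + k)
    fit <- fit_mixture(x, k = k, settings = scaled_mcmc_settings(seed = k))
    expect_true(all(fit$mu[, -1, drop = FALSE] >=
                      fit$mu[, -k, drop = FALSE]))
    expect_equal(rowSums(fit$w), rep(1, nrow(fit$w)), tolerance = 1e-12)
  }
  expect_error(mixture_fit(mu = cbind(c(2, 2), c(1, 3)),
                           sigma = matrix(1, 2, 2),
                           w = matrix(0.5, 2, 2)),
               "ascending")
})

test_that("draws are bit-reproducible under fixed seed and settings", {
  x <- two_group_log_bp(seed = 41, n_per_group = 40L)
  f1 <- fit_mixture(x, 2, settings = scaled_mcmc_settings(seed = 9))
  f2 <- fit_mixture(x, 2, settings = scaled_mcmc_settings(seed = 9))
  expect_identical(f1$mu, f2$mu)
  expect_identical(f1$sigma, f2$sigma)
  expect_identical(f1$waic, f2$waic)
})

test_that("WAIC is deterministic given draws and prefers the true K", {
  x <- two_group_log_bp(seed = 51)
  fit2 <- fit_mixture(x, 2, settings = scaled_mcmc_settings(seed = 3))
  expect_identical(compute_waic(fit2), compute_waic(fit2))
  fit1 <- fit_mixture(x, 1, settings = scaled_mcmc_settings(seed = 3))
  expect_lt(fit2$waic, fit1$waic)
  expect_error(compute_waic(fit2, log_values = x[1:10]), "match")
  sel <- select_mixture_k(x, k_range = 1:2,
                          settings = scaled_mcmc_settings(seed = 4))
  expect_equal(sel$best_k, 2)
})

test_that("Gelman-Rubin follows the closed-form PSRF", {
  # duplicated chains: between-chain variance 0, statistic at its floor
  set.seed(1)
  ch <- rnorm(1000)
  n <- length(ch)
  expect_equal(gelman_rubin(cbind(ch, ch)), sqrt((n - 1) / n))
  # hand-computed PSRF for two offset chains (means 0 and 10, within-SD 1)
  set.seed(2)
  a <- rnorm(100); a <- (a - mean(a)) / sd(a)       # mean 0, var 1 exactly
  b <- a + 10
  W <- 1
  B <- 100 * var(c(0, 10))
  expect_equal(gelman_rubin(cbind(a, b)),
               sqrt(((99 / 100) * W + B / 100) / W))
  expect_gt(gelman_rubin(cbind(a, b)), 5)
  expect_error(gelman_rubin(matrix(rnorm(10), ncol = 1)), "2 chains")
  expect_error(gelman_rubin(list(1:3, 1:4)), "equal length")
})

test_that("posterior membership rows sum to 1 and respect separation", {
  # separation limit: components 10 SDs apart, value at a component mean
  fit <- point_mass_mixture(mu = c(0, 10), sigma = c(1, 1), w = c(0.5, 0.5))
  m <- posterior_membership(fit, exp(c(0, 10)))
  expect_gt(m[1, 1], 0.9999)
  expect_gt(m[2, 2], 0.9999)

  x <- two_group_log_bp(seed = 61)
  fit2 <- fit_mixture(x, 2, settings = scaled_mcmc_settings(seed = 5))
  memb <- posterior_membership(fit2, exp(x))
  expect_equal(rowSums(memb), rep(1, length(x)), tolerance = 1e-9)
  expect_true(all(memb >= 0 & memb <= 1))
  expect_error(posterior_membership(fit2, c(10, 0)), "positive")
})

test_that("cluster labelling names the highest mean pregnant", {
  fit2 <- point_mass_mixture(mu = c(1.0, 5.9), sigma = c(1, 1),
                             w = c(0.5, 0.5))
  expect_equal(label_clusters(fit2), c("non_pregnant", "pregnant"))
  fit3 <- point_mass_mixture(mu = c(0, 3, 6), sigma = c(1, 1, 1),
                             w = rep(1 / 3, 3))
  expect_equal(label_clusters(fit3),
               c("non_pregnant", "intermediate", "pregnant"))
  fit1 <- point_mass_mixture(mu = 2, sigma = 1, w = 1)
  expect_warning(lab <- label_clusters(fit1), "undifferentiated")
  expect_equal(lab, "undifferentiated")
  expect_equal(fit3$pregnant_cluster, 3)
})

test_that("fit_mixture rejects bad inputs", {
  expect_error(fit_mixture(c(1, 2, NA), 2,
                           settings = scaled_mcmc_settings()), "finite")
  expect_error(fit_mixture(c(1, 2), 2, settings = scaled_mcmc_settings()),
               "more observations")
  expect_error(fit_mixture(1:10, 0, settings = scaled_mcmc_settings()),
               "positive integer")
})
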