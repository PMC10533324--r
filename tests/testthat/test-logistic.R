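test_that("status coding sends recent-parturition females to prediction", {
  resp <- logistic_response(c("pregnant", "lactating", "resting",
                              "immature_male", "mature_male",
                              "immature_female", "recent_parturition",
                              "unknown"))
  expect_equal(resp, c(1L, 0L, 0L, 0L, 0L, 0L, NA, NA))
  expect_error(logistic_response("gestating"), "unrecognised")
})

test_that("a null effect yields an odds-ratio interval containing 1", {
  set.seed(10)
  x <- rnorm(200, 3, 1)
  y <- rbinom(200, 1, 0.5)  # labels independent of BP
  fit <- fit_logistic(x, y, settings = scaled_mcmc_settings(seed = 10))
  expect_lt(fit$odds_ratio["lower"], 1)
  expect_gt(fit$odds_ratio["upper"], 1)
})

test_that("single-class training errors and separation warns", {
  expect_error(fit_logistic(1:10, rep(1, 10),
                            settings = scaled_mcmc_settings()),
               "both pregnant and non-pregnant")
  x <- c(rnorm(20, 0, 0.5), rnorm(20, 10, 0.5))
  y <- rep(c(0, 1), each = 20)
  expect_warning(fit_logistic(x, y, settings = scaled_mcmc_settings(seed = 2)),
                 "separated")
})

test_that("missing responses receive posterior predictive probabilities", {
  set.seed(3)
  x <- c(runif(100, 0, 3), runif(100, 4, 7), c(0.5, 6.5))
  y <- c(rbinom(100, 1, plogis(-8 + 2 * x[1:100])),
         rbinom(100, 1, plogis(-8 + 2 * x[101:200])), NA, NA)
  fit <- fit_logistic(x, y, settings = scaled_mcmc_settings(seed = 4))
  expect_equal(nrow(fit$predicted), 2)
  expect_true(all(fit$predicted$probability >= 0 &
                    fit$predicted$probability <= 1))
  # monotone when the slope posterior is positive
  expect_true(all(fit$beta1 > 0))
  expect_lt(fit$predicted$probability[1], fit$predicted$probability[2])
})

test_that("probability dichotomisation is boundary-inclusive at the cutoff", {
  expect_equal(classify_by_probability(c(0.49, 0.50, 1.0)),
               c("non_pregnant", "pregnant", "pregnant"))
  expect_error(classify_by_probability(0.5, cutoff = 0), "0, 1")
  expect_error(classify_by_probability(0.5, cutoff = 1), "0, 1")
  expect_error(classify_by_probability(1.2), "0, 1")
})

test_that("equal-odds concentration inverts the linear predictor", {
  # closed form: point-mass draws
  expect_equal(equal_odds_point(logistic_fit(-4.6052, 1))$mean,
               exp(4.6052))
  expect_equal(equal_odds_point(logistic_fit(0, 2))$mean, 1)
  # per-draw identity: probability at the equal-odds point is exactly 0.5
  set.seed(5)
  fit <- logistic_fit(rnorm(200, -8, 1), rnorm(200, 2, 0.2))
  eo <- equal_odds_point(fit)
  p_at_eo <- plogis(fit$beta0 + fit$beta1 * log(eo$draws))
  expect_equal(p_at_eo, rep(0.5, 200), tolerance = 1e-12)
  # slope draws straddling zero are rejected
  expect_error(equal_odds_point(logistic_fit(c(-1, -1), c(-0.1, 0.1))),
               "straddle")
})

test_that("logistic draws are reproducible and diagnosable", {
  set.seed(6)
  x <- rnorm(100, 3, 1.5)
  y <- rbinom(100, 1, plogis(-6 + 2 * x))
  f1 <- fit_logistic(x, y, settings = scaled_mcmc_settings(seed = 7))
  f2 <- fit_logistic(x, y, settings = scaled_mcmc_settings(seed = 7))
  expect_identical(f1$beta0, f2$beta0)
  expect_identical(f1$beta1, f2$beta1)
  expect_true(all(f1$rhat < 1.1))
})
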