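test_that("group_spec validates its fields and names the offending group", {
  expect_error(group_spec("pregnant", n = -1, mean_raw = 365, sd_raw = 244),
               "pregnant.*non-negative integer")
  expect_error(group_spec("resting", n = 5, mean_raw = 0, sd_raw = 1),
               "resting.*positive")
  expect_error(group_spec("resting", n = 5, mean_raw = -3, sd_raw = 1),
               "resting")
  expect_error(group_spec("resting", n = 5, mean_raw = 3, sd_raw = -1),
               "non-negative")
})

test_that("simulate_known_samples handles degenerate inputs", {
  empty <- simulate_known_samples(list(), seed = 1)
  expect_s3_class(empty, "data.frame")
  expect_equal(nrow(empty), 0)

  point <- simulate_known_samples(
    group_spec("pregnant", 1000, mean_raw = 365, sd_raw = 0), seed = 1)
  expect_true(all(point$bp_tissue_ng_g == 365))
  expect_equal(unique(point$status), "pregnant")
})

test_that("lognormal moment matching reproduces raw-scale moments", {
  # oracle: the closed-form moment map, checked by direct simulation at n=1e4
  tab <- simulate_known_samples(
    group_spec("pregnant", 10000, mean_raw = 365, sd_raw = 244), seed = 99)
  se_mean <- 244 / sqrt(10000)
  expect_lt(abs(mean(tab$bp_tissue_ng_g) - 365), 2 * se_mean)
  expect_lt(abs(sd(tab$bp_tissue_ng_g) - 244) / 244, 0.05)

  p <- lognormal_params(365, 244)
  expect_equal(exp(p$meanlog + p$sdlog^2 / 2), 365)
  expect_equal(sqrt((exp(p$sdlog^2) - 1)) * 365, 244)
})

test_that("the built-in reference groups carry the validation-sample moments", {
  specs <- reference_group_specs()
  expect_length(specs, 7)
  means <- vapply(specs, `[[`, numeric(1), "mean_raw")
  expect_equal(unname(means),
               c(1.1, 0.8, 0.6, 3.1, 365, 273, 38.4))
  ns <- vapply(specs, `[[`, numeric(1), "n")
  expect_equal(sum(ns), 62)
})

test_that("tables are bit-identical under a fixed seed", {
  a <- simulate_known_samples(two_group_specs(), seed = 5)
  b <- simulate_known_samples(two_group_specs(), seed = 5)
  expect_identical(a, b)
  c <- simulate_unknown_population(biopsy_population_spec(), 200, seed = 5)
  d <- simulate_unknown_population(biopsy_population_spec(), 200, seed = 5)
  expect_identical(c, d)
  expect_false(identical(
    a, simulate_known_samples(two_group_specs(), seed = 6)))
})

test_that("unknown-population draws follow the mixing weights", {
  spec1 <- population_spec(
    components = two_group_specs(1L), weights = c(1, 0),
    lipid_mean = 0.243, lipid_sd = 0.1,
    colour_proportions = c(grey = 0.25, off_white = 0.2, white = 0.55))
  pop1 <- simulate_unknown_population(spec1, 50, seed = 2)
  expect_true(all(pop1$latent_truth == "resting"))

  spec2 <- population_spec(
    components = two_group_specs(1L), weights = c(0.5, 0.5),
    lipid_mean = 0.243, lipid_sd = 0.1,
    colour_proportions = c(grey = 0.25, off_white = 0.2, white = 0.55))
  pop2 <- simulate_unknown_population(spec2, 10000, seed = 2)
  # binomial SE oracle: sqrt(.5*.5/1e4) = 0.005
  expect_lt(abs(mean(pop2$latent_truth == "pregnant") - 0.5), 2 * 0.005)
  # biopsy-like lipid level
  expect_lt(abs(mean(pop2$lipid_fraction) - 0.243), 0.01)

  expect_error(simulate_unknown_population(spec2, -1, seed = 1),
               "non-negative")
})

test_that("lipid fractions match Beta moments and stay in (0, 1]", {
  expect_equal(simulate_lipid_fractions(5, mean = 0.3, sd = 0, seed = 1),
               rep(0.3, 5))
  x <- simulate_lipid_fractions(10000, mean = 0.664, sd = 0.1, seed = 31)
  expect_true(all(x > 0 & x <= 1))
  # Beta moment oracle: SE of the mean = 0.1/sqrt(1e4)
  expect_lt(abs(mean(x) - 0.664) , 2 * 0.1 / sqrt(10000))
  expect_lt(abs(sd(x) - 0.1) / 0.1, 0.1)
  expect_error(simulate_lipid_fractions(10, mean = 0.5, sd = 0.6, seed = 1),
               "infeasible")
  # program contrast built into the default specs: carcass vs biopsy lipid
  ratio <- carcass_population_spec()$lipid_mean /
    biopsy_population_spec()$lipid_mean
  expect_gt(ratio, 2.5)
  expect_lt(ratio, 2.9)
})

test_that("latent truth is confined to its own column", {
  pop <- simulate_unknown_population(biopsy_population_spec(), 100, seed = 8)
  expect_true(all(pop$status == "unknown"))
  # the columns classifiers read carry no label information
  classifier_cols <- c("bp_tissue_ng_g", "bp_lipid_ng_g", "lipid_fraction",
                       "colour_class", "sex", "program")
  for (col in classifier_cols) {
    expect_false(any(pop[[col]] %in% pop$latent_truth))
  }
  expect_true("latent_truth" %in% names(pop))
})
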