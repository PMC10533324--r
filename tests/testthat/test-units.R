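test_that("assay back-calculation follows the ELISA unit chain", {
  expect_equal(adjust_assay_concentration(0, blubber_mass = 0.1), 0)
  # hand calculation: 100 pg/mL * 0.5 mL / 1000 = 0.05 ng; / 0.1 g = 0.5
  expect_equal(
    adjust_assay_concentration(100, buffer_volume = 0.5, dilution_factor = 1,
                               recovery_fraction = 1, blubber_mass = 0.1),
    0.5)
  # dividing by the carcass-assay recovery of 88.3%
  expect_equal(
    adjust_assay_concentration(100, recovery_fraction = 0.883,
                               blubber_mass = 0.1),
    0.5 / 0.883)
  expect_error(adjust_assay_concentration(100, recovery_fraction = 0,
                                          blubber_mass = 0.1), "recovery")
  expect_error(adjust_assay_concentration(100, recovery_fraction = 1,
                                          blubber_mass = 0), "mass")
  expect_error(adjust_assay_concentration(-1, blubber_mass = 0.1),
               "non-negative")
})

test_that("assay back-calculation is monotone in each argument", {
  base <- adjust_assay_concentration(100, dilution_factor = 5,
                                     recovery_fraction = 0.883,
                                     blubber_mass = 0.1)
  expect_gt(adjust_assay_concentration(110, dilution_factor = 5,
                                       recovery_fraction = 0.883,
                                       blubber_mass = 0.1), base)
  expect_gt(adjust_assay_concentration(100, dilution_factor = 6,
                                       recovery_fraction = 0.883,
                                       blubber_mass = 0.1), base)
  expect_lt(adjust_assay_concentration(100, dilution_factor = 5,
                                       recovery_fraction = 0.95,
                                       blubber_mass = 0.1), base)
  expect_lt(adjust_assay_concentration(100, dilution_factor = 5,
                                       recovery_fraction = 0.883,
                                       blubber_mass = 0.12), base)
})

test_that("tissue/lipid conversion divides by the lipid fraction", {
  expect_equal(tissue_to_lipid(100, 1), 100)
  expect_equal(tissue_to_lipid(100, 0.25), 400)
  expect_equal(tissue_to_lipid(100, 0.664), 100 / 0.664)
  expect_error(tissue_to_lipid(100, 0), "0, 1")
  # round trip to machine precision, across magnitudes
  bp <- c(0.1, 3.1, 55, 365, 878)
  lf <- c(0.05, 0.243, 0.5, 0.664, 1)
  expect_equal(tissue_to_lipid(bp, lf) * lf, bp)
  # per-lipid never below per-tissue
  expect_true(all(tissue_to_lipid(bp, lf) >= bp))
})

test_that("lipid imputation fills only missing values and flags them", {
  tab <- data.frame(lipid_fraction = c(NA, 0.30, NA))
  out <- impute_lipid_fraction(tab, fallback = 0.664)
  expect_equal(out$lipid_fraction, c(0.664, 0.30, 0.664))
  expect_equal(out$lipid_imputed, c(TRUE, FALSE, TRUE))
  empty <- impute_lipid_fraction(data.frame(lipid_fraction = numeric(0)))
  expect_equal(nrow(empty), 0)
})

test_that("low-lipid exclusion is boundary-inclusive and partitions", {
  tab <- data.frame(lipid_fraction = c(0.04, 0.05, 0.051, NA, 0.3))
  parts <- filter_low_lipid(tab, min_fraction = 0.05)
  expect_equal(parts$excluded$lipid_fraction, c(0.04, 0.05))
  expect_equal(nrow(parts$retained) + nrow(parts$excluded), nrow(tab))
  # partition property under random tables
  for (seed in 1:5) {
    pop <- simulate_unknown_population(biopsy_population_spec(), 200,
                                       seed = seed)
    parts <- filter_low_lipid(pop, 0.05)
    expect_equal(nrow(parts$retained) + nrow(parts$excluded), 200)
    expect_true(all(parts$excluded$lipid_fraction <= 0.05))
    expect_true(all(parts$retained$lipid_fraction > 0.05))
  }
})

test_that("log transform is the natural log and rejects non-positives", {
  expect_equal(log_bp(1), 0)
  expect_equal(log_bp(55), 4.0, tolerance = 0.01)  # ln 55 = 4.007
  expect_equal(log_bp(100), 4.6052, tolerance = 1e-4)
  expect_error(log_bp(c(1, 0)), "detection")
  expect_error(log_bp(-5), "positive")
  expect_equal(log_bp(floor_detection_limit(c(0, 0.05, 55))),
               log(c(0.1, 0.1, 55)))
})
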