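test_that("expected mature counts apply the colour-class schedule", {
  expect_equal(expected_mature_count(
    colour_counts("white", 0, 0))$total, 0)
  # canonical field counts: 30+3 white, 9+3 off-white, 12+3 grey
  cc <- colour_counts(c("white", "off_white", "grey"),
                      biopsied = c(30, 9, 12), virtual = c(3, 3, 3))
  out <- expected_mature_count(cc, maturity_schedule())
  expect_equal(out$per_class$expected_mature, c(33, 12, 4.2))
  expect_equal(out$total, 49.2)
  expect_equal(out$total_rounded, 49)
  # grey only: 10 biopsied at 10% maturity
  expect_equal(expected_mature_count(
    colour_counts("grey", 10, 0), maturity_schedule())$total, 1.0)
  expect_error(expected_mature_count(
    colour_counts("white_ish", 5, 0), maturity_schedule()), "missing")
})

test_that("expected pregnant count applies the three-year cycle", {
  expect_equal(as.numeric(expected_pregnant_count(0)), 0)
  expect_equal(as.numeric(expected_pregnant_count(49, 1 / 3)), 16)
  expect_equal(as.numeric(expected_pregnant_count(56, 1 / 3)), 19)
  expect_lt(abs(attr(expected_pregnant_count(49), "unrounded") -
                  expected_pregnant_count(49)), 1)
})

test_that("the maturity correction lowers the rate as published", {
  est <- adjusted_pregnancy_rate(20, 45, c(white = 7, off_white = 3,
                                           grey = 5), maturity_schedule())
  expect_equal(est$additional_mature, 11)  # round(7 + 3 + 0.5), half up
  expect_equal(est$raw_rate, 20 / 45)
  expect_equal(est$adjusted_rate, 20 / 56)
  expect_equal(round(100 * est$raw_rate, 1), 44.4)
  expect_equal(round(100 * est$adjusted_rate, 1), 35.7)

  # no unknown-maturity females: adjusted equals raw
  same <- adjusted_pregnancy_rate(20, 45, numeric(0))
  expect_equal(same$adjusted_rate, same$raw_rate)
  # all probabilities 1: everyone joins the denominator
  all1 <- adjusted_pregnancy_rate(10, 20, c(white = 5, off_white = 2),
                                  maturity_schedule(grey = 1))
  expect_equal(all1$additional_mature, 7)
  expect_error(adjusted_pregnancy_rate(30, 20, numeric(0)), "min_mature")
  expect_error(adjusted_pregnancy_rate(5, 0, numeric(0)), "denominator")
})

test_that("the estimate is invariant to consistent colour relabelling", {
  sched_a <- maturity_schedule(white = 1, off_white = 0.8, grey = 0.1)
  a <- adjusted_pregnancy_rate(10, 30, c(white = 4, off_white = 2, grey = 6),
                               sched_a)
  # swap the roles of white and grey everywhere
  sched_b <- maturity_schedule(white = 0.1, off_white = 0.8, grey = 1)
  b <- adjusted_pregnancy_rate(10, 30, c(grey = 4, off_white = 2, white = 6),
                               sched_b)
  expect_equal(a$adjusted_rate, b$adjusted_rate)
  expect_equal(a$additional_mature, b$additional_mature)
  # adjusted never exceeds raw
  expect_lte(a$adjusted_rate, a$raw_rate)
})

test_that("rates assemble from a classified sample table", {
  n <- 40
  tab <- data.frame(
    colour_class = rep(c("white", "grey"), each = n / 2),
    is_virtual = c(rep(FALSE, n - 4), rep(TRUE, 4))
  )
  labels <- c(rep("pregnant", 10), rep("intermediate", 6),
              rep("non_pregnant", 20), rep(NA, 4))
  est <- pregnancy_rate_from_labels(tab, labels, maturity_schedule())
  expect_equal(est$n_pregnant, 10)
  expect_equal(est$min_mature, 10 + 6 + 4)
  expect_equal(est$raw_rate, 10 / 20)
  expect_s3_class(est, "pregnancy_rate_estimate")
  expect_output(print(est), "adjusted")
})
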