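test_that("reliability is the true-score share of observed variance", {
  expect_equal(reliability_from_components(1.0, 1.0), 0.5)
  expect_equal(reliability_from_components(1.0, 0.0), 1.0)
  # the worked example's first group: sigma_X2 = 0.31 at rho = 0.92
  expect_equal(reliability_from_components(0.2852, 0.0248), 0.92,
               tolerance = 1e-12)
  expect_error(reliability_from_components(0, 0), class = "reliapower_config_error")
  expect_error(reliability_from_components(-1, 2), class = "reliapower_config_error")
})

test_that("variance_components enforces the additive identity and rho bounds", {
  vc <- variance_components(0.2852, 0.0248)
  expect_equal(vc$sigma_X2, vc$sigma_T2 + vc$sigma_E2, tolerance = 1e-12)
  expect_equal(vc$rho, vc$sigma_T2 / vc$sigma_X2, tolerance = 1e-12)
  expect_equal(variance_components(2, 0)$rho, 1)
  expect_equal(variance_components(0, 2)$rho, 0)
})

test_that("fixed-variance calibrations invert reliability correctly", {
  expect_equal(error_variance_fixed_true(0.5), 1.0)
  expect_equal(error_variance_fixed_true(1.0), 0.0)
  expect_equal(error_variance_fixed_true(0.2), 4.0)
  expect_error(error_variance_fixed_true(0), class = "reliapower_config_error")
  expect_error(error_variance_fixed_true(1.2), class = "reliapower_config_error")

  expect_equal(true_variance_fixed_error(0.0), 0.0)
  expect_equal(true_variance_fixed_error(0.5), 1.0)
  expect_equal(true_variance_fixed_error(0.9), 9.0)
  expect_error(true_variance_fixed_error(1), class = "reliapower_config_error")

  # monotone in opposite directions: the root of the power paradox
  rho <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(vapply(rho, error_variance_fixed_true, 0)) < 0))
  expect_true(all(diff(vapply(rho, true_variance_fixed_error, 0)) > 0))
})

test_that("decompose_observed reproduces the worked example's error variances", {
  c1 <- decompose_observed(0.31, 0.92)
  c2 <- decompose_observed(0.05, 0.57)
  expect_equal(c1$sigma_E2, 0.0248, tolerance = 1e-12)
  expect_equal(c2$sigma_E2, 0.0215, tolerance = 1e-12)
  expect_equal(round_display(c1$sigma_E2), 0.025)
  expect_equal(round_display(c2$sigma_E2), 0.022)
  # the counterintuitive direction: higher-reliability group has MORE error
  expect_gt(c1$sigma_E2, c2$sigma_E2)
  expect_equal(decompose_observed(3.7, 1.0)$sigma_E2, 0)
})

test_that("decompose/recompose round-trips reliability exactly", {
  for (rho in seq(0, 1, by = 0.05)) {
    for (sx2 in c(0.05, 0.31, 1, 7)) {
      vc <- decompose_observed(sx2, rho)
      expect_equal(reliability_from_components(vc$sigma_T2, vc$sigma_E2),
                   rho, tolerance = 1e-12)
    }
  }
})

test_that("Spearman-Brown projects half-test correlations to full length", {
  expect_equal(spearman_brown(1.0), 1.0)
  expect_equal(spearman_brown(0.0), 0.0)
  expect_equal(spearman_brown(0.8518519), 0.92, tolerance = 1e-6)
  expect_lt(spearman_brown(-0.2), 0)       # passed through, not clipped
  expect_error(spearman_brown(-1), class = "reliapower_config_error")
})

test_that("Spearman-Brown of the half-test correlation recovers full reliability", {
  # half scores carry twice the full-score error variance, so the half-half
  # correlation is sT2/(sT2 + 2 sE2); projecting it must give sT2/(sT2 + sE2)
  for (sT2 in c(0.01, 0.0285, 0.2852, 1, 5)) {
    for (sE2 in c(0.005, 0.0215, 0.0248, 1, 3)) {
      r_half <- sT2 / (sT2 + 2 * sE2)
      expect_equal(spearman_brown(r_half), sT2 / (sT2 + sE2),
                   tolerance = 1e-12)
    }
  }
})

test_that("display rounding is half-away-from-zero at three decimals", {
  expect_equal(round_display(0.05 - 0.57 * 0.05), 0.022)
  expect_equal(round_display(0.31 - 0.92 * 0.31), 0.025)
  expect_equal(round_display(-0.0215), -0.022)
  expect_equal(round_display(1.23449), 1.234)
  expect_equal(sd_to_var(var_to_sd(0.31)), 0.31, tolerance = 1e-15)
})
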