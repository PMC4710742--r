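test_that("exact power matches a large-sample noncentral-t simulation", {
  # Oracle: 1e6 draws of (Z + ncp)/sqrt(chisq_df/df) at N = 30, delta = 0.5,
  # sigma = 1, one-sided alpha = 0.05 (paper layout) gave 0.847985 with
  # binomial SE 0.00036; frozen with a 3-SE tolerance.
  p <- exact_power(power_spec(N = 30, delta = 0.5, alpha = 0.05, sigma = 1))
  expect_equal(p, 0.847985, tolerance = 0.0011)
})

test_that("power approaches the significance level as the effect vanishes", {
  for (tails in c("one_sided", "two_sided")) {
    deltas <- 10^seq(-1, -6)
    pows <- vapply(deltas, function(d)
      exact_power(power_spec(N = 30, delta = d, sigma = 1, tails = tails)), 0)
    expect_true(all(diff(pows) < 0))
    expect_equal(pows[length(pows)], 0.05, tolerance = 1e-4)
  }
  # same limit when noise swamps the effect
  p <- exact_power(power_spec(N = 30, delta = 0.5, sigma = 1e6))
  expect_equal(p, 0.05, tolerance = 1e-4)
})

test_that("power specs reject out-of-domain parameters", {
  expect_error(power_spec(N = 30, delta = 0, sigma = 1),
               class = "reliapower_config_error")
  expect_error(power_spec(N = 1, delta = 0.5, sigma = 1),
               class = "reliapower_config_error")
  expect_error(power_spec(N = 30, delta = 0.5, alpha = 0, sigma = 1),
               class = "reliapower_config_error")
  expect_error(power_spec(N = 30, delta = 0.5, sigma = 0),
               class = "reliapower_config_error")
})

test_that("power is bounded by the level below and one above", {
  set.seed(5)
  for (i in 1:50) {
    spec <- power_spec(N = sample(2:80, 1), delta = runif(1, 0.01, 2),
                       alpha = runif(1, 0.001, 0.2),
                       sigma = runif(1, 0.1, 5))
    p <- exact_power(spec)
    expect_gte(p, spec$alpha)
    expect_lte(p, 1)   # saturates to 1 in floating point at huge effects
  }
  # away from saturation the bound is strict
  expect_lt(exact_power(power_spec(N = 50, delta = 1, sigma = 1)), 1)
})

test_that("power is nondecreasing in N under both calibrations and layouts", {
  for (formula in c("paper", "standard_two_sample")) {
    for (scenario in c("fixed_true", "fixed_error")) {
      rho <- if (scenario == "fixed_true") c(0.3, 0.9) else c(0.1, 0.7)
      s <- power_surface(scenario, rho, N_grid = seq(5, 100, by = 5),
                         formula = formula)
      expect_true(all(apply(s$power, 1, function(row) all(diff(row) >= 0))))
    }
  }
})

test_that("fixed true-score variance makes power rise with reliability", {
  s <- power_surface("fixed_true", fig1_rho, fig_N)
  expect_true(all(apply(s$power, 2, function(col) all(diff(col) > 0))))
  # perfectly reliable column is the sigma = 1 calculation
  ref <- vapply(fig_N, function(N)
    exact_power(power_spec(N = N, delta = 0.5, sigma = 1)), 0)
  expect_equal(unname(s$power[nrow(s$power), ]), ref, tolerance = 1e-12)
})

test_that("fixed error-score variance makes power fall with reliability", {
  s <- power_surface("fixed_error", fig2_rho, fig_N)
  expect_true(all(apply(s$power, 2, function(col) all(diff(col) < 0))))
})

test_that("both t layouts agree on the direction of the relationship", {
  for (formula in c("paper", "standard_two_sample")) {
    up <- power_surface("fixed_true", fig1_rho, fig_N, formula = formula)
    dn <- power_surface("fixed_error", fig2_rho, fig_N, formula = formula)
    expect_true(all(apply(up$power, 2, function(col) all(diff(col) > 0))))
    expect_true(all(apply(dn$power, 2, function(col) all(diff(col) < 0))))
  }
})

test_that("surface construction rejects reliabilities outside the scenario", {
  expect_error(power_surface("fixed_true", c(0.5, 0), fig_N), "0")
  expect_error(power_surface("fixed_error", c(0.5, 1), fig_N), "1")
  expect_error(power_surface("fixed_true", numeric(0), fig_N),
               class = "reliapower_config_error")
})

test_that("surfaces serialize to long CSV and JSON with config attached", {
  s <- power_surface("fixed_true", c(0.5, 1.0), c(10, 20))
  df <- as.data.frame(s)
  expect_equal(nrow(df), 4)
  expect_named(df, c("scenario", "rho", "N", "delta", "alpha", "tails",
                     "formula", "power"))
  expect_true(all(df$power >= 0 & df$power <= 1))

  csv <- tempfile(fileext = ".csv"); json <- tempfile(fileext = ".json")
  write_power_surface(s, csv = csv, json = json)
  back <- read.csv(csv)
  expect_equal(back$power, df$power, tolerance = 1e-12)
  parsed <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(parsed$config$scenario, "fixed_true")
  expect_equal(parsed$config$alpha, 0.05)
})
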