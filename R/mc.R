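#' Monte Carlo replication probability
#'
#' Simulates repeated two-condition experiments and reports the fraction
#' reaching significance — the replication-probability estimate that the
#' exact non-central-t formula replaces. Scores are generated under the
#' classical test model: each simulated observation is a true-score draw
#' plus an independent error draw, with the variance components set by the
#' chosen calibration (`fixed_true`: `sigma_T2 = 1`,
#' `sigma_E2 = (1 - rho)/rho`; `fixed_error`: `sigma_E2 = 1`,
#' `sigma_T2 = rho/(1 - rho)`).
#'
#' The simulated test matches the layout of the spec's `formula`: the
#' `"paper"` layout simulates the corresponding one-sample design (N scores
#' with mean `delta`, t against zero on `N - 1` df), while
#' `"standard_two_sample"` simulates two independent groups of N whose means
#' differ by `delta` and applies the pooled-variance t on `2(N - 1)` df.
#' The oracle must simulate exactly what the formula computes.
#'
#' @param spec a [power_spec] giving N, delta, alpha, tails and layout. The
#'   spec's `sigma` is ignored: the observed-score SD is implied by
#'   `scenario` and `rho`.
#' @param scenario `"fixed_true"` or `"fixed_error"`.
#' @param rho reliability, in the scenario's valid domain.
#' @param reps number of simulated experiments, `>= 1` (default 10000).
#' @param seed integer RNG seed; required so every run is auditable.
#' @param delta0 optional true mean difference override; set to 0 to
#'   estimate the type-I error rate while keeping the spec's critical value.
#' @return An object of class `mc_result`: `p_sig` (proportion significant),
#'   `reps`, `mc_se` (binomial standard error `sqrt(p(1-p)/reps)`), and the
#'   resolved configuration including the seed.
#' @examples
#' spec <- power_spec(N = 30, delta = 0.5)
#' mc_power(spec, "fixed_true", rho = 0.5, reps = 2000, seed = 1)
#' @export
mc_power <- function(spec, scenario = c("fixed_true", "fixed_error"), rho,
                     reps = 10000, seed, delta0 = NULL) {
  if (!inherits(spec, "power_spec")) stop_config("spec must be a power_spec")
  scenario <- match.arg(scenario)
  check_number(rho, "rho", lower = 0, upper = 1)
  check_number(reps, "reps", lower = 1)
  if (missing(seed)) stop_config("seed is required for mc_power")
  check_number(seed, "seed")
  reps <- as.integer(reps)

  sigma2 <- scenario_sigma2(scenario, rho)
  if (scenario == "fixed_true") {
    sT2 <- 1.0; sE2 <- sigma2 - 1.0
  } else {
    sE2 <- 1.0; sT2 <- sigma2 - 1.0
  }
  delta <- if (is.null(delta0)) spec$delta else delta0
  N <- spec$N

  set.seed(seed)
  draw_scores <- function(mu) {
    matrix(mu + stats::rnorm(N * reps, sd = sqrt(sT2)) +
             stats::rnorm(N * reps, sd = sqrt(sE2)), nrow = N)
  }
  col_sd2 <- function(m) (colSums(m^2) - colSums(m)^2 / N) / (N - 1)

  if (spec$formula == "paper") {
    x <- draw_scores(delta)
    mbar <- colMeans(x)
    tstat <- mbar / sqrt(col_sd2(x) / N)
    df <- N - 1
  } else {
    x1 <- draw_scores(0)
    x2 <- draw_scores(delta)
    sp2 <- (col_sd2(x1) + col_sd2(x2)) / 2
    tstat <- (colMeans(x2) - colMeans(x1)) / sqrt(2 * sp2 / N)
    df <- 2 * (N - 1)
  }
  p <- if (spec$tails == "two_sided")
    2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  else
    stats::pt(tstat, df, lower.tail = FALSE)

  p_sig <- mean(p < spec$alpha)
  structure(list(p_sig = p_sig, reps = reps,
                 mc_se = sqrt(p_sig * (1 - p_sig) / reps),
                 config = list(N = N, delta = delta, alpha = spec$alpha,
                               tails = spec$tails, formula = spec$formula,
                               scenario = scenario, rho = rho,
                               sigma2 = sigma2, seed = seed)),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("Monte Carlo replication probability: %.4f (SE %.4f, %d reps)\n",
              x$p_sig, x$mc_se, x$reps))
  cfg <- x$config
  cat(sprintf("  N = %d, delta = %g, alpha = %g, %s, rho = %g, %s, seed = %d\n",
              cfg$N, cfg$delta, cfg$alpha, cfg$scenario, cfg$rho,
              cfg$formula, as.integer(cfg$seed)))
  if (x$reps < 2) cat("  note: reps < 2, standard error is degenerate\n")
  invisible(x)
}
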