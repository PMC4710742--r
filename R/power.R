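#' Specify a two-group power calculation
#'
#' Collects the design parameters of the two-condition mean comparison:
#' per-condition sample size `N`, smallest relevant mean difference `delta`,
#' significance level `alpha`, within-group observed-score standard
#' deviation `sigma`, tail convention, and which degrees-of-freedom /
#' noncentrality layout to use.
#'
#' Two layouts are supported. `formula = "paper"` follows the printed power
#' function literally: `N - 1` degrees of freedom with noncentrality
#' `sqrt(N) * delta / sigma`, the layout of a one-sample or paired design.
#' `formula = "standard_two_sample"` uses the usual equal-n two-independent-
#' groups layout: `2 * (N - 1)` degrees of freedom with noncentrality
#' `sqrt(N / 2) * delta / sigma`. Both produce the same qualitative
#' reliability-power relationships; absolute power differs.
#'
#' @param N observations per condition, integer `>= 2`.
#' @param delta smallest relevant mean difference, `> 0` (score units).
#' @param alpha significance level, in `(0, 1)`.
#' @param sigma within-group observed-score standard deviation, `> 0`.
#' @param tails `"one_sided"` (default; the printed formula uses a single
#'   upper critical value) or `"two_sided"` (splits `alpha` over both tails).
#' @param formula `"paper"` (default) or `"standard_two_sample"`; see Details.
#' @return An object of class `power_spec`.
#' @examples
#' power_spec(N = 30, delta = 0.5, sigma = 1)
#' @export
power_spec <- function(N, delta, alpha = 0.05, sigma = 1,
                       tails = c("one_sided", "two_sided"),
                       formula = c("paper", "standard_two_sample")) {
  tails <- match.arg(tails)
  formula <- match.arg(formula)
  check_number(N, "N", lower = 2)
  if (N != round(N)) stop_config("N must be a whole number")
  check_number(delta, "delta", lower = 0, open_lower = TRUE)
  check_number(alpha, "alpha", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  check_number(sigma, "sigma", lower = 0, open_lower = TRUE)
  structure(list(N = as.integer(N), delta = delta, alpha = alpha,
                 sigma = sigma, tails = tails, formula = formula),
            class = "power_spec")
}

#' @export
print.power_spec <- function(x, ...) {
  cat(sprintf("Power spec: N = %d per condition, delta = %g, alpha = %g, sigma = %g\n",
              x$N, x$delta, x$alpha, x$sigma))
  cat(sprintf("  tails = %s, layout = %s\n", x$tails, x$formula))
  invisible(x)
}

# df, noncentrality and central-t critical value implied by a power_spec
t_layout <- function(spec) {
  if (spec$formula == "paper") {
    df <- spec$N - 1
    ncp <- sqrt(spec$N) * spec$delta / spec$sigma
  } else {
    df <- 2 * (spec$N - 1)
    ncp <- sqrt(spec$N / 2) * spec$delta / spec$sigma
  }
  a <- if (spec$tails == "two_sided") spec$alpha / 2 else spec$alpha
  list(df = df, ncp = ncp, tcrit = stats::qt(1 - a, df))
}

#' Exact power of the two-group mean comparison
#'
#' Evaluates the rejection probability of the t test analytically through
#' the non-central t distribution: with critical value `t_crit` (the upper
#' `alpha` quantile of the central t, or upper `alpha/2` if two-sided),
#' power is `1 - F(t_crit)` where `F` is the CDF of the non-central t with
#' the layout's degrees of freedom and noncentrality. For a two-sided test
#' the (usually negligible) lower-tail rejection region `F(-t_crit)` is
#' included, so that at `delta -> 0` the size equals `alpha` under either
#' tail convention.
#'
#' @param spec a [power_spec].
#' @return Power, a single value in `[0, 1]`.
#' @examples
#' exact_power(power_spec(N = 30, delta = 0.5, sigma = 1))
#' @export
exact_power <- function(spec) {
  if (!inherits(spec, "power_spec")) stop_config("spec must be a power_spec")
  lay <- t_layout(spec)
  p <- stats::pt(lay$tcrit, df = lay$df, ncp = lay$ncp, lower.tail = FALSE)
  if (spec$tails == "two_sided")
    p <- p + stats::pt(-lay$tcrit, df = lay$df, ncp = lay$ncp)
  unname(p)
}

# observed-score variance implied by reliability under each calibration
scenario_sigma2 <- function(scenario, rho) {
  if (scenario == "fixed_true") {
    bad <- rho <= 0 | rho > 1
    if (any(bad))
      stop_config("fixed_true requires rho in (0, 1]; offending rho: ",
                  paste(rho[bad], collapse = ", "))
    1 + (1 - rho) / rho        # sigma_T2 = 1, sigma_E2 = (1 - rho)/rho
  } else {
    bad <- rho < 0 | rho >= 1
    if (any(bad))
      stop_config("fixed_error requires rho in [0, 1); offending rho: ",
                  paste(rho[bad], collapse = ", "))
    1 / (1 - rho)              # sigma_E2 = 1, sigma_T2 = rho/(1 - rho)
  }
}

#' Exact power over a reliability-by-sample-size grid
#'
#' Computes the power surface behind the two calibrations that make the
#' reliability-power "paradox" visible. Under `scenario = "fixed_true"` the
#' true-score variance is pinned at 1.0 and the observed variance grows as
#' reliability falls (`sigma^2 = 1 + (1 - rho) / rho`), so power increases
#' with reliability. Under `scenario = "fixed_error"` the error variance is
#' pinned at 1.0 and the observed variance grows as reliability rises
#' (`sigma^2 = 1 / (1 - rho)`), so power *decreases* with reliability.
#'
#' @param scenario `"fixed_true"` or `"fixed_error"`.
#' @param rho_grid reliabilities; must lie in the scenario's domain
#'   (`(0, 1]` for fixed_true, `[0, 1)` for fixed_error).
#' @param N_grid per-condition sample sizes.
#' @param delta,alpha,tails,formula as in [power_spec].
#' @return An object of class `power_surface`: the power matrix (rows
#'   indexed by `rho_grid`, columns by `N_grid`) plus the grid metadata.
#' @examples
#' s <- power_surface("fixed_true", rho_grid = seq(0.1, 1, 0.1),
#'                    N_grid = seq(10, 50, 10))
#' print(s)
#' @export
power_surface <- function(scenario = c("fixed_true", "fixed_error"),
                          rho_grid, N_grid,
                          delta = 0.5, alpha = 0.05,
                          tails = c("one_sided", "two_sided"),
                          formula = c("paper", "standard_two_sample")) {
  scenario <- match.arg(scenario)
  tails <- match.arg(tails)
  formula <- match.arg(formula)
  if (length(rho_grid) < 1 || length(N_grid) < 1)
    stop_config("rho_grid and N_grid must be non-empty")
  sigma2 <- scenario_sigma2(scenario, rho_grid)
  power <- matrix(NA_real_, length(rho_grid), length(N_grid),
                  dimnames = list(rho = format(rho_grid), N = format(N_grid)))
  for (j in seq_along(N_grid)) {
    for (i in seq_along(rho_grid)) {
      spec <- power_spec(N = N_grid[j], delta = delta, alpha = alpha,
                         sigma = sqrt(sigma2[i]), tails = tails,
                         formula = formula)
      power[i, j] <- exact_power(spec)
    }
  }
  structure(list(scenario = scenario, rho_grid = rho_grid, N_grid = N_grid,
                 delta = delta, alpha = alpha, tails = tails,
                 formula = formula, power = power),
            class = "power_surface")
}

#' @export
print.power_surface <- function(x, digits = 3, ...) {
  cat(sprintf("Exact power surface, %s variance fixed at 1.00\n",
              if (x$scenario == "fixed_true") "true-score" else "error-score"))
  cat(sprintf("  delta = %g, alpha = %g, %s, layout = %s\n",
              x$delta, x$alpha, x$tails, x$formula))
  print(round(x$power, digits), ...)
  invisible(x)
}

#' @export
as.data.frame.power_surface <- function(x, ...) {
  grid <- expand.grid(rho = x$rho_grid, N = x$N_grid,
                      KEEP.OUT.ATTRS = FALSE)
  data.frame(scenario = x$scenario, rho = grid$rho, N = grid$N,
             delta = x$delta, alpha = x$alpha, tails = x$tails,
             formula = x$formula, power = as.vector(x$power))
}

#' @export
plot.power_surface <- function(x, ...) {
  graphics::matplot(x$rho_grid, x$power, type = "b", pch = 19, lty = 1,
                    xlab = expression(rho[XX * minute]), ylab = "Power",
                    ylim = c(0, 1),
                    main = sprintf("Exact power, %s variance fixed",
                                   if (x$scenario == "fixed_true") "true-score"
                                   else "error-score"), ...)
  graphics::legend("right", legend = paste("N =", x$N_grid),
                   col = seq_along(x$N_grid), lty = 1, pch = 19, bty = "n")
  invisible(x)
}

#' Write a power surface to CSV and/or JSON
#'
#' The CSV is the long-format table (columns scenario, rho, N, delta, alpha,
#' tails, formula, power); the JSON bundles the same values with the full
#' resolved configuration for audit.
#'
#' @param x a [power_surface].
#' @param csv,json output paths; `NULL` skips that format.
#' @return Invisibly, the written paths.
#' @export
write_power_surface <- function(x, csv = NULL, json = NULL) {
  if (!inherits(x, "power_surface")) stop_config("x must be a power_surface")
  df <- as.data.frame(x)
  if (!is.null(csv))
    utils::write.csv(df, csv, row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(json)) {
    payload <- list(
      schema = "reliapower/power_surface/v1",
      config = x[c("scenario", "rho_grid", "N_grid", "delta", "alpha",
                   "tails", "formula")],
      power = df)
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(c(csv = csv, json = json))
}
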