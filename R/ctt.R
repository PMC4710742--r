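#' Classical test theory variance algebra
#'
#' Under the classical test model an observed score is the sum of an
#' unobserved true score and an independent error score, `X = T + E`.
#' Reliability is the proportion of observed-score variance attributable to
#' true scores, `rho = sigma_T2 / (sigma_T2 + sigma_E2)`. These helpers
#' convert between the four quantities (`sigma_T2`, `sigma_E2`, `sigma_X2`,
#' `rho`) in every direction used when calibrating power analyses and
#' decomposing group summaries.
#'
#' @param sigma_T2 true-score variance (score units squared), `>= 0`.
#' @param sigma_E2 error-score variance (score units squared), `>= 0`.
#' @name ctt
NULL

#' Construct a set of variance components
#'
#' Bundles a true-score variance and an error-score variance into a
#' `variance_components` object holding the implied observed variance and
#' reliability. The components must be non-negative population parameters;
#' sampling-noise estimates slightly outside the parameter space are not
#' accepted here (estimate containers carry their own contracts).
#'
#' @inheritParams ctt
#' @return An object of class `variance_components`: a list with elements
#'   `sigma_T2`, `sigma_E2`, `sigma_X2` and `rho`.
#' @examples
#' variance_components(1, 1)        # reliability 0.5
#' decompose_observed(0.31, 0.92)   # error variance 0.0248
#' @export
variance_components <- function(sigma_T2, sigma_E2) {
  check_number(sigma_T2, "sigma_T2", lower = 0)
  check_number(sigma_E2, "sigma_E2", lower = 0)
  sigma_X2 <- sigma_T2 + sigma_E2
  if (sigma_X2 <= 0)
    stop_config("reliability is undefined when both variance components are zero")
  structure(
    list(sigma_T2 = sigma_T2, sigma_E2 = sigma_E2,
         sigma_X2 = sigma_X2, rho = sigma_T2 / sigma_X2),
    class = "variance_components")
}

#' @export
print.variance_components <- function(x, digits = 4, ...) {
  cat("Variance components (X = T + E)\n")
  cat(sprintf("  sigma_T2 = %s  sigma_E2 = %s  sigma_X2 = %s\n",
              format(x$sigma_T2, digits = digits),
              format(x$sigma_E2, digits = digits),
              format(x$sigma_X2, digits = digits)))
  cat(sprintf("  reliability rho = %s\n", format(x$rho, digits = digits)))
  invisible(x)
}

#' @export
as.data.frame.variance_components <- function(x, ...) {
  data.frame(sigma_T2 = x$sigma_T2, sigma_E2 = x$sigma_E2,
             sigma_X2 = x$sigma_X2, rho = x$rho)
}

#' Reliability from variance components
#'
#' @inheritParams ctt
#' @return The reliability `sigma_T2 / (sigma_T2 + sigma_E2)`, in `[0, 1]`.
#' @examples
#' reliability_from_components(1, 1)  # 0.5
#' @export
reliability_from_components <- function(sigma_T2, sigma_E2) {
  variance_components(sigma_T2, sigma_E2)$rho
}

#' Error variance implied by a reliability when true-score variance is fixed
#'
#' In the fixed-true-score-variance calibration the true-score variance is
#' held constant (1.0 by default) and the error variance is chosen to hit a
#' target reliability: `sigma_E2 = sigma_T2 * (1 - rho) / rho`.
#'
#' @param rho target reliability, in `(0, 1]`.
#' @param sigma_T2 fixed true-score variance, default 1.
#' @return The implied error-score variance.
#' @examples
#' error_variance_fixed_true(0.5)  # 1
#' error_variance_fixed_true(0.2)  # 4
#' @export
error_variance_fixed_true <- function(rho, sigma_T2 = 1.0) {
  check_number(rho, "rho", lower = 0, upper = 1, open_lower = TRUE)
  check_number(sigma_T2, "sigma_T2", lower = 0)
  sigma_T2 * (1 - rho) / rho
}

#' True-score variance implied by a reliability when error variance is fixed
#'
#' In the fixed-error-score-variance calibration the error variance is held
#' constant (1.0 by default) and the true-score variance varies with the
#' target reliability: `sigma_T2 = sigma_E2 * rho / (1 - rho)`. The implied
#' observed variance is `sigma_E2 / (1 - rho)`.
#'
#' @param rho target reliability, in `[0, 1)`.
#' @param sigma_E2 fixed error-score variance, default 1.
#' @return The implied true-score variance.
#' @examples
#' true_variance_fixed_error(0.9)  # 9
#' @export
true_variance_fixed_error <- function(rho, sigma_E2 = 1.0) {
  check_number(rho, "rho", lower = 0, upper = 1, open_upper = TRUE)
  check_number(sigma_E2, "sigma_E2", lower = 0)
  sigma_E2 * rho / (1 - rho)
}

#' Decompose an observed variance given a reliability
#'
#' Splits an observed-score variance into true-score and error-score parts:
#' `sigma_T2 = rho * sigma_X2`, `sigma_E2 = sigma_X2 - rho * sigma_X2`. This
#' is the arithmetic behind per-group error-variance reports: a group with
#' observed variance 0.31 and reliability 0.92 carries error variance
#' 0.0248, displayed as 0.025 at three decimals.
#'
#' @param sigma_X2 observed-score variance, `>= 0`.
#' @param rho reliability, in `[0, 1]`.
#' @return A [variance_components] object.
#' @examples
#' decompose_observed(0.31, 0.92)
#' decompose_observed(0.05, 0.57)
#' @export
decompose_observed <- function(sigma_X2, rho) {
  check_number(sigma_X2, "sigma_X2", lower = 0, open_lower = TRUE)
  check_number(rho, "rho", lower = 0, upper = 1)
  variance_components(sigma_T2 = rho * sigma_X2,
                      sigma_E2 = sigma_X2 - rho * sigma_X2)
}

#' Spearman-Brown projection of a half-test correlation
#'
#' Projects the correlation `r` between two parallel half-tests to the
#' reliability of the full-length test: `2 r / (1 + r)`. Negative inputs are
#' passed through (the projection can be negative for `r < 0`); no clipping
#' is applied.
#'
#' @param r half-test correlation(s), each in `(-1, 1]`. Vectorised.
#' @return The projected full-test reliability, same length as `r`.
#' @examples
#' spearman_brown(0.8518519)  # ~0.92
#' @export
spearman_brown <- function(r) {
  if (!is.numeric(r) || any(!is.finite(r)))
    stop_config("r must be finite numeric")
  if (any(r <= -1) || any(r > 1))
    stop_config("half-test correlation must lie in (-1, 1]")
  2 * r / (1 + r)
}

#' Convert between standard deviations and variances
#'
#' Group summaries are usually reported as standard deviations while the
#' variance algebra works on variances; these helpers make the conversion
#' explicit so the two scales are never mixed silently.
#'
#' @param sd standard deviation(s), `>= 0`.
#' @param var variance(s), `>= 0`.
#' @return `sd_to_var` returns `sd^2`; `var_to_sd` returns `sqrt(var)`.
#' @export
sd_to_var <- function(sd) {
  if (any(sd < 0)) stop_config("sd must be non-negative")
  sd^2
}

#' @rdname sd_to_var
#' @export
var_to_sd <- function(var) {
  if (any(var < 0)) stop_config("var must be non-negative")
  sqrt(var)
}

#' Round for display, half away from zero
#'
#' Report tables display variances to three decimals with halves rounded
#' away from zero (0.0215 displays as 0.022). A 1e-8 guard absorbs binary
#' representation error at the half boundary; raw values are always kept
#' unrounded alongside the display values.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 3).
#' @return `x` rounded half-away-from-zero to `digits` decimals.
#' @examples
#' round_display(0.05 - 0.57 * 0.05)  # 0.022
#' @export
round_display <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-8) / p
}
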