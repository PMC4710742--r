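#' Summarise one group
#'
#' @param label group name.
#' @param n group size, integer `>= 2`.
#' @param mean sample mean (score units).
#' @param sd sample standard deviation, n-1 denominator, `>= 0`.
#' @return An object of class `group_summary` with `label`, `n`, `mean`,
#'   `sd` and `variance` (`sd^2`).
#' @export
group_summary <- function(label, n, mean, sd) {
  if (!is.character(label) || length(label) != 1L)
    stop_config("label must be a single string")
  check_number(n, "n", lower = 2)
  if (n != round(n)) stop_config("n must be a whole number")
  check_number(mean, "mean")
  check_number(sd, "sd", lower = 0)
  structure(list(label = label, n = as.integer(n), mean = mean, sd = sd,
                 variance = sd^2),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%s: n = %d, M = %g, SD = %g\n", x$label, x$n, x$mean, x$sd))
  invisible(x)
}

#' Welch two-sample comparison from group summaries
#'
#' The unequal-variances t test:
#' `t = (mean2 - mean1) / sqrt(s1^2/n1 + s2^2/n2)`, with
#' Welch-Satterthwaite degrees of freedom
#' `(s1^2/n1 + s2^2/n2)^2 / ((s1^2/n1)^2/(n1-1) + (s2^2/n2)^2/(n2-1))` and
#' the p-value from the central t with that df. With equal variances and
#' equal n the df reduce to `2(n - 1)` exactly (Student's test).
#'
#' @param g1,g2 [group_summary] objects; the statistic is oriented as
#'   group 2 minus group 1.
#' @param tails `"two_sided"` (default) or `"one_sided"` (upper tail of
#'   `mean2 - mean1`).
#' @return An object of class `welch_test`: `t`, `df`, `p`, `tails`,
#'   `groups` (the two summaries).
#' @examples
#' welch_from_summaries(group_summary("irrelevant", 30, -0.25, 0.55),
#'                      group_summary("relevant", 30, 0.68, 0.22))
#' @export
welch_from_summaries <- function(g1, g2,
                                 tails = c("two_sided", "one_sided")) {
  tails <- match.arg(tails)
  if (!inherits(g1, "group_summary") || !inherits(g2, "group_summary"))
    stop_config("g1 and g2 must be group_summary objects")
  v1 <- g1$variance / g1$n
  v2 <- g2$variance / g2$n
  if (v1 + v2 == 0)
    stop_degenerate("both group variances are zero; t is undefined")
  tstat <- (g2$mean - g1$mean) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  p <- if (tails == "two_sided") 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
       else stats::pt(tstat, df, lower.tail = FALSE)
  structure(list(t = tstat, df = df, p = p, tails = tails,
                 groups = list(g1, g2)),
            class = "welch_test")
}

#' Welch two-sample comparison from raw scores
#'
#' Computes each group's summary (sample SD, n-1 denominator) and delegates
#' to [welch_from_summaries()].
#'
#' @param scores1,scores2 numeric score vectors, each of length `>= 2`.
#' @param tails as in [welch_from_summaries()].
#' @param labels length-2 character vector of group names.
#' @return A `welch_test`.
#' @export
welch_from_scores <- function(scores1, scores2,
                              tails = c("two_sided", "one_sided"),
                              labels = c("group1", "group2")) {
  tails <- match.arg(tails)
  if (length(scores1) < 2 || length(scores2) < 2)
    stop_config("each group needs at least 2 scores")
  g1 <- group_summary(labels[1], length(scores1), mean(scores1),
                      stats::sd(scores1))
  g2 <- group_summary(labels[2], length(scores2), mean(scores2),
                      stats::sd(scores2))
  welch_from_summaries(g1, g2, tails = tails)
}

#' @export
print.welch_test <- function(x, ...) {
  cat("Welch two-sample comparison\n")
  for (g in x$groups) print(g)
  cat(sprintf("  t(%.2f) = %.2f, p %s (%s)\n", x$df, x$t,
              if (x$p < 0.001) "< 0.001" else sprintf("= %.3f", x$p),
              x$tails))
  invisible(x)
}

#' Per-group error-variance decomposition report
#'
#' For each group, splits the observed variance into true-score and
#' error-score parts given a reliability estimate
#' (`sigma_E2 = sigma_X2 - rho * sigma_X2`). This is the check that a lower
#' reliability does not necessarily mean more measurement error: a group
#' with observed variance 0.31 and reliability 0.92 carries *more* error
#' variance (0.025) than a group with observed variance 0.05 and
#' reliability 0.57 (0.022); the reliability gap is driven by true-score
#' variance.
#'
#' @param summaries list of [group_summary] objects.
#' @param reliabilities numeric vector of reliability estimates, one per
#'   group.
#' @return A data.frame (class `group_error_report`) with per-group raw
#'   components and 3-decimal display columns.
#' @examples
#' group_error_report(
#'   list(group_summary("irrelevant", 30, -0.25, sqrt(0.31)),
#'        group_summary("relevant", 30, 0.68, sqrt(0.05))),
#'   c(0.92, 0.57))
#' @export
group_error_report <- function(summaries, reliabilities) {
  if (inherits(summaries, "group_summary")) summaries <- list(summaries)
  if (length(summaries) != length(reliabilities))
    stop_config("summaries and reliabilities must have equal length")
  rows <- Map(function(g, rho) {
    comp <- decompose_observed(g$variance, rho)
    data.frame(label = g$label, n = g$n, mean = g$mean, sd = g$sd,
               sigma_X2 = comp$sigma_X2, rho = rho,
               sigma_T2 = comp$sigma_T2, sigma_E2 = comp$sigma_E2,
               sigma_T2_display = round_display(comp$sigma_T2),
               sigma_E2_display = round_display(comp$sigma_E2))
  }, summaries, reliabilities)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("group_error_report", "data.frame")
  out
}

#' @export
print.group_error_report <- function(x, ...) {
  cat("Per-group variance decomposition (3-decimal display values)\n")
  show <- data.frame(group = x$label, n = x$n, M = x$mean, SD = x$sd,
                     rho = x$rho,
                     sigma_T2 = x$sigma_T2_display,
                     sigma_E2 = x$sigma_E2_display)
  print.data.frame(show, row.names = FALSE, ...)
  invisible(x)
}
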