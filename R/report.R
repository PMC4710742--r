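#' Run the power-curve analysis and write its outputs
#'
#' Convenience runner around [power_surface()]: computes the surface on the
#' standard grids (reliability 0.10-1.00 for `fixed_true`, 0.00-0.90 for
#' `fixed_error`, in steps of 0.10; N in 10-50 by 10; `alpha = 0.05`,
#' `delta = 0.5`) and, when `out_dir` is given, writes `power_surface_*.csv`
#' and `.json` (with the resolved configuration embedded) and optionally a
#' PDF figure with one line per N. Data files are the canonical outputs;
#' the figure is optional so nothing depends on a graphics device.
#'
#' @param scenario `"fixed_true"` or `"fixed_error"`.
#' @param out_dir output directory, created if needed; `NULL` writes nothing.
#' @param rho_grid,N_grid grids; defaults are the standard ones above.
#' @param delta,alpha,tails,formula as in [power_spec()].
#' @param plot write a PDF figure (requires `out_dir`).
#' @return The [power_surface], invisibly when `out_dir` is given.
#' @export
run_power_curve <- function(scenario = c("fixed_true", "fixed_error"),
                            out_dir = NULL, rho_grid = NULL,
                            N_grid = seq(10, 50, by = 10),
                            delta = 0.5, alpha = 0.05,
                            tails = "one_sided", formula = "paper",
                            plot = FALSE) {
  scenario <- match.arg(scenario)
  if (is.null(rho_grid))
    rho_grid <- if (scenario == "fixed_true") seq(0.1, 1.0, by = 0.1)
                else seq(0.0, 0.9, by = 0.1)
  surf <- power_surface(scenario, rho_grid, N_grid, delta = delta,
                        alpha = alpha, tails = tails, formula = formula)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    base <- file.path(out_dir, paste0("power_surface_", scenario))
    write_power_surface(surf, csv = paste0(base, ".csv"),
                        json = paste0(base, ".json"))
    if (plot) {
      grDevices::pdf(paste0(base, ".pdf"), width = 7, height = 5)
      on.exit(grDevices::dev.off(), add = TRUE)
      plot(surf)
    }
    return(invisible(surf))
  }
  surf
}

#' Check the Monte Carlo simulator against the exact power formula
#'
#' Runs [mc_power()] on every cell of a reliability-by-N grid, joins the
#' estimates with [exact_power()], and reports per-cell z-scores
#' `(p_sig - exact) / mc_se` together with the fraction of cells within 3
#' Monte Carlo standard errors. Each cell gets its own seed derived from
#' the base seed so the whole table is reproducible.
#'
#' @param scenario,rho_grid,N_grid,delta,alpha,tails,formula as in
#'   [run_power_curve()].
#' @param reps simulated experiments per cell (default 10000).
#' @param seed base integer seed (cell i uses `seed + i`).
#' @param out_dir output directory; `NULL` writes nothing.
#' @return An object of class `mc_check`: the per-cell data.frame
#'   (`$cells`), the coverage summary (`$prop_within_3se`), and the
#'   resolved config.
#' @export
run_mc_check <- function(scenario = c("fixed_true", "fixed_error"),
                         rho_grid = NULL, N_grid = seq(10, 50, by = 10),
                         delta = 0.5, alpha = 0.05, tails = "one_sided",
                         formula = "paper", reps = 10000, seed,
                         out_dir = NULL) {
  scenario <- match.arg(scenario)
  if (missing(seed)) stop_config("seed is required for run_mc_check")
  if (is.null(rho_grid))
    rho_grid <- if (scenario == "fixed_true") seq(0.1, 1.0, by = 0.1)
                else seq(0.0, 0.9, by = 0.1)
  grid <- expand.grid(rho = rho_grid, N = N_grid, KEEP.OUT.ATTRS = FALSE)
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sigma <- sqrt(scenario_sigma2(scenario, grid$rho[i]))
    spec <- power_spec(N = grid$N[i], delta = delta, alpha = alpha,
                       sigma = sigma, tails = tails, formula = formula)
    ex <- exact_power(spec)
    mc <- mc_power(spec, scenario, grid$rho[i], reps = reps, seed = seed + i)
    z <- if (mc$mc_se > 0) (mc$p_sig - ex) / mc$mc_se else NA_real_
    res[[i]] <- data.frame(scenario = scenario, rho = grid$rho[i],
                           N = grid$N[i], exact = ex, p_sig = mc$p_sig,
                           mc_se = mc$mc_se, z = z,
                           within_3se = is.finite(z) && abs(z) <= 3,
                           seed = seed + i)
  }
  cells <- do.call(rbind, res)
  out <- structure(
    list(cells = cells,
         prop_within_3se = mean(cells$within_3se),
         config = list(scenario = scenario, rho_grid = rho_grid,
                       N_grid = N_grid, delta = delta, alpha = alpha,
                       tails = tails, formula = formula, reps = reps,
                       seed = seed)),
    class = "mc_check")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cells,
                     file.path(out_dir, paste0("mc_check_", scenario, ".csv")),
                     row.names = FALSE, fileEncoding = "UTF-8")
    jsonlite::write_json(
      list(schema = "reliapower/mc_check/v1", config = out$config,
           prop_within_3se = out$prop_within_3se),
      file.path(out_dir, paste0("mc_check_", scenario, ".json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(out))
  }
  out
}

#' @export
print.mc_check <- function(x, ...) {
  cat(sprintf("Monte Carlo vs exact power: %d cells, %s scenario, %d reps/cell\n",
              nrow(x$cells), x$config$scenario, x$config$reps))
  cat(sprintf("  %.1f%% of cells within 3 Monte Carlo SEs of the exact value\n",
              100 * x$prop_within_3se))
  if (x$config$reps < 2)
    cat("  note: reps < 2, Monte Carlo standard errors are degenerate\n")
  invisible(x)
}

#' Run the two-condition worked example end to end
#'
#' Generates the synthetic instruction experiment, moment-matches each
#' condition's full scores to the printed group summaries (mean -0.25 /
#' SD 0.55 and mean 0.68 / SD 0.22 by default), estimates each condition's
#' reliability with the 1000-split Spearman-Brown bootstrap, compares the
#' group means with a Welch test, and decomposes each group's observed
#' variance into true- and error-score parts using the bootstrap
#' reliability estimates.
#'
#' @param seed integer seed driving the generator and the bootstrap.
#' @param specs list of [condition_spec]s (default: the two-condition
#'   instruction experiment).
#' @param targets moment-matching targets (`condition`, `mean`, `sd`);
#'   `NULL` skips moment matching (population mode).
#' @param n_splits bootstrap splits per condition (default 1000).
#' @param tails tail convention for the Welch test.
#' @param out_dir output directory; when given, writes `worked_example.json`
#'   (the machine-readable report, timestamps excluded so identical seeds
#'   give byte-identical files), `trial_table.csv`, and optionally a
#'   practice-vs-test scatterplot PDF.
#' @param plot write the scatterplot PDF (requires `out_dir`).
#' @return An object of class `iat_report` bundling the trial table, group
#'   summaries, split-half results, Welch result and the error-variance
#'   report.
#' @examples
#' rep <- run_worked_example(seed = 7, n_splits = 100)
#' print(rep)
#' @export
run_worked_example <- function(seed, specs = default_condition_specs(),
                               targets = data.frame(
                                 condition = c("attitude_irrelevant",
                                               "attitude_relevant"),
                                 mean = c(-0.25, 0.68),
                                 sd = c(0.55, 0.22)),
                               n_splits = 1000, tails = "two_sided",
                               out_dir = NULL, plot = FALSE) {
  if (missing(seed)) stop_config("seed is required for run_worked_example")
  tab <- generate_experiment(specs, seed = seed)
  if (!is.null(targets)) tab <- moment_match(tab, targets)

  conditions <- vapply(specs, `[[`, "", "label")
  rel <- lapply(conditions, function(cond)
    split_half_bootstrap(tab, cond, n_splits = n_splits))
  names(rel) <- conditions

  fs <- full_scores(tab)
  summaries <- lapply(conditions, function(cond) {
    x <- fs$score[fs$condition == cond]
    group_summary(cond, length(x), mean(x), stats::sd(x))
  })
  welch <- welch_from_summaries(summaries[[1]], summaries[[2]], tails = tails)
  err <- group_error_report(summaries,
                            vapply(rel, `[[`, 0.0, "sb_estimate"))

  report <- structure(
    list(config = list(schema = "reliapower/worked_example/v1", seed = seed,
                       n_splits = n_splits, tails = tails,
                       moment_matched = !is.null(targets),
                       specs = lapply(specs, unclass),
                       targets = targets),
         trial_table = tab, reliability = rel, welch = welch,
         error_report = err),
    class = "iat_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trial_table(tab, file.path(out_dir, "trial_table.csv"))
    payload <- list(
      config = report$config,
      groups = lapply(summaries, unclass),
      welch = list(t = welch$t, df = welch$df, p = welch$p,
                   tails = welch$tails),
      reliability = lapply(rel, function(r)
        list(condition = r$condition, n_splits = r$n_splits,
             mean_r = r$mean_r, sb_estimate = r$sb_estimate,
             excluded_splits = r$excluded_splits, seed = r$seed)),
      error_report = as.data.frame(unclass(err), stringsAsFactors = FALSE))
    jsonlite::write_json(payload, file.path(out_dir, "worked_example.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    if (plot) {
      grDevices::pdf(file.path(out_dir, "practice_vs_test.pdf"),
                     width = 6, height = 6)
      on.exit(grDevices::dev.off(), add = TRUE)
      plot(report)
    }
    return(invisible(report))
  }
  report
}

#' @export
print.iat_report <- function(x, ...) {
  cat("Two-condition IAT worked example",
      sprintf("(seed %d%s)\n", as.integer(x$config$seed),
              if (x$config$moment_matched) ", moment-matched" else ""))
  print(x$welch)
  for (r in x$reliability)
    cat(sprintf("  %s: bootstrap split-half reliability = %.2f (mean r = %.2f)\n",
                r$condition, r$sb_estimate, r$mean_r))
  print(x$error_report)
  invisible(x)
}

#' @export
summary.iat_report <- function(object, ...) {
  print(object, ...)
}

#' Practice-half vs test-half scatterplot
#'
#' Plots each participant's mean practice-block score against their mean
#' test-block score, one symbol per condition (the scatter view of how the
#' two instruction conditions separate and how consistently the two block
#' types rank participants).
#'
#' @param x an `iat_report`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.iat_report <- function(x, ...) {
  tab <- x$trial_table
  halves <- stats::aggregate(score ~ participant_id + condition + block,
                             data = tab, FUN = mean)
  wide <- stats::reshape(halves, idvar = c("participant_id", "condition"),
                         timevar = "block", direction = "wide")
  conds <- unique(wide$condition)
  pch <- ifelse(wide$condition == conds[1], 19, 21)
  graphics::plot(wide$score.practice, wide$score.test, pch = pch,
                 xlab = "IAT score, practice trials",
                 ylab = "IAT score, test trials", ...)
  graphics::abline(stats::lm(score.test ~ score.practice, data = wide),
                   lty = 2)
  graphics::legend("topleft", legend = conds, pch = c(19, 21), bty = "n")
  invisible(x)
}
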