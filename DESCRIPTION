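Package: reliapower
Title: Reliability, Statistical Power, and Replicability Under Classical Test Theory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the relation (and non-relation) between the
    reliability of a measure and the statistical power of a two-group mean
    comparison. Implements the classical-test-theory variance algebra
    (true-score, error-score and observed variance, reliability, the
    Spearman-Brown projection), exact power of the two-group t comparison via
    the non-central t distribution under fixed true-score-variance and fixed
    error-score-variance calibrations, a seeded Monte Carlo replication
    simulator that serves as a stochastic oracle for the exact formula, a
    synthetic trial-level generator for a two-condition Implicit Association
    Test experiment, bootstrap split-half reliability estimation with
    Spearman-Brown correction, and Welch two-sample inference with per-group
    error-variance decomposition reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
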