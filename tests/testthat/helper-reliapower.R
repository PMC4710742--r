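# Shared fixtures, built in code.

# Score vector of length n with sample mean exactly m and sample SD exactly s
# (n-1 denominator); used to hand welch oracles raw data matching a summary.
make_scores_exact <- function(n, m, s) {
  z <- as.numeric(scale(seq_len(n) + sin(seq_len(n))))
  m + s * z
}

# Minimal trial table built by hand (bypasses the generator) for edge cases.
as_trial_table <- function(df) {
  structure(df, class = c("trial_table", "data.frame"))
}

hand_trial_table <- function(scores_by_participant, condition = "c1") {
  K <- length(scores_by_participant[[1]])
  rows <- do.call(rbind, lapply(seq_along(scores_by_participant), function(i)
    data.frame(participant_id = sprintf("p%02d", i), condition = condition,
               block = rep(c("practice", "test"), each = K / 2),
               trial_index = seq_len(K),
               score = scores_by_participant[[i]],
               stringsAsFactors = FALSE)))
  as_trial_table(rows)
}

fig1_rho <- seq(0.1, 1.0, by = 0.1)
fig2_rho <- seq(0.0, 0.9, by = 0.1)
fig_N <- seq(10, 50, by = 10)
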