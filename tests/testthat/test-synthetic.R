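test_that("the default experiment has the study's design", {
  tab <- generate_experiment(seed = 1)
  expect_s3_class(tab, "trial_table")
  expect_setequal(unique(tab$condition),
                  c("attitude_irrelevant", "attitude_relevant"))
  counts <- table(tab$participant_id)
  expect_length(counts, 60)                       # 30 per condition
  expect_true(all(counts == 40))                  # 2 blocks x 20 trials
  expect_true(all(counts %% 2 == 0))              # splittable
  expect_setequal(unique(tab$block), c("practice", "test"))
  expect_false(anyNA(tab$score))
})

test_that("generation is deterministic given the seed", {
  a <- generate_experiment(seed = 123)
  b <- generate_experiment(seed = 123)
  c <- generate_experiment(seed = 124)
  expect_identical(a$score, b$score)
  expect_false(identical(a$score, c$score))
})

test_that("a perfectly reliable condition has zero trial-level noise", {
  sp <- condition_spec("pure", mu = 0.3, sigma_X2 = 0.2, rho = 1, n = 5,
                       trials_per_block = 4)
  tab <- generate_experiment(list(sp), seed = 2)
  spread <- tapply(tab$score, tab$participant_id, function(x) diff(range(x)))
  expect_true(all(spread == 0))
})

test_that("full scores are the per-participant trial means", {
  tab <- hand_trial_table(list(rep(0.5, 4), c(0, 1, 0, 1)))
  fs <- full_scores(tab)
  expect_equal(fs$score, c(0.5, 0.5))
  one <- hand_trial_table(list(c(0, 1)))
  expect_equal(full_scores(one)$score, 0.5)
})

test_that("sample means track the population means across seeds", {
  specs <- default_condition_specs()
  hits <- matrix(FALSE, 100, 2)
  for (s in 1:100) {
    fs <- full_scores(generate_experiment(specs, seed = 9000 + s))
    for (j in 1:2) {
      sp <- specs[[j]]
      m <- mean(fs$score[fs$condition == sp$label])
      hits[s, j] <- abs(m - sp$mu) <= 3 * sqrt(sp$sigma_X2 / sp$n)
    }
  }
  # 3-sigma bound: expect essentially all seeds inside, allow rare tail hits
  expect_gte(sum(hits), 196)
})

test_that("the generator is calibrated: full scores have the target variance", {
  sp <- condition_spec("cal", mu = 0.68, sigma_X2 = 0.05, rho = 0.57, n = 30)
  v <- vapply(1:300, function(s) {
    fs <- full_scores(generate_experiment(list(sp), seed = 20000 + s))
    var(fs$score)
  }, 0)
  expect_lt(abs(mean(v) - 0.05) / 0.05, 0.05)     # within 5% of sigma_X2
})

test_that("moment matching hits the printed summaries exactly", {
  tab <- generate_experiment(seed = 31)
  targets <- data.frame(condition = c("attitude_irrelevant", "attitude_relevant"),
                        mean = c(-0.25, 0.68), sd = c(0.55, 0.22))
  fs <- full_scores(moment_match(tab, targets))
  for (i in 1:2) {
    x <- fs$score[fs$condition == targets$condition[i]]
    expect_equal(mean(x), targets$mean[i], tolerance = 1e-10)
    expect_equal(sd(x), targets$sd[i], tolerance = 1e-10)
  }
})

test_that("moment matching is the identity at the current moments", {
  tab <- generate_experiment(seed = 32)
  fs <- full_scores(tab)
  x <- fs$score[fs$condition == "attitude_relevant"]
  same <- moment_match(tab, data.frame(condition = "attitude_relevant",
                                       mean = mean(x), sd = sd(x)))
  expect_equal(same$score, tab$score, tolerance = 1e-12)
})

test_that("moment matching rejects degenerate data", {
  flat <- hand_trial_table(list(rep(1, 4), rep(1, 4), rep(1, 4)))
  expect_error(moment_match(flat, data.frame(condition = "c1", mean = 0, sd = 1)),
               class = "reliapower_degenerate_error")
  tab <- generate_experiment(seed = 33)
  expect_error(moment_match(tab, data.frame(condition = "attitude_relevant",
                                            mean = 0, sd = 0)),
               class = "reliapower_config_error")
})

test_that("the moment-matched experiment reproduces the Welch arithmetic", {
  rep <- run_worked_example(seed = 7, n_splits = 50)
  expect_equal(rep$welch$t, 8.599078, tolerance = 1e-4)
  expect_equal(rep$welch$df, 38.04836, tolerance = 1e-4)
})

test_that("trial tables round-trip through CSV", {
  tab <- generate_experiment(seed = 40)
  path <- tempfile(fileext = ".csv")
  write_trial_table(tab, path)
  back <- read_trial_table(path)
  expect_equal(back$score, tab$score, tolerance = 1e-10)
  expect_identical(back$participant_id, tab$participant_id)
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_trial_table(bad), class = "reliapower_config_error")
})
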