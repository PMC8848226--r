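# Crossover analysis battery.

test_that("paired t handles identical samples and the closed-form example", {
  x <- c(4, 5, 6, 7)
  r0 <- paired_t(x, x)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # differences (1, 2, 3): t = 2 / (1 / sqrt(3)) = 3.4641, p ~ 0.0742
  r <- paired_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-6)
  expect_equal(r$p_value, 0.0742, tolerance = 1e-3)
  expect_equal(r$effect, 2)
  expect_equal(r$effect_sd, 1)
})

test_that("paired t rejects malformed pairs", {
  expect_error(paired_t(1:3, 1:4), class = "cervgame_validation_error")
  expect_error(paired_t(1, 2), class = "cervgame_validation_error")
  expect_error(paired_t(c(1, NA, 3), 1:3), class = "cervgame_validation_error")
  # constant non-zero differences: zero variance, t undefined
  expect_error(paired_t(c(2, 3, 4), c(1, 2, 3)), class = "cervgame_validation_error")
})

test_that("Wilcoxon signed-rank statistic matches hand enumeration", {
  # differences (1, -2, 3, -4, 5): positive ranks 1, 3, 5 -> V = 9
  x <- c(1, 0, 3, 0, 5); y <- c(0, 2, 0, 4, 0)
  r <- wilcoxon_signed(x, y)
  expect_equal(unname(r$statistic), 9)
  # all-zero differences: degenerate, no rejection
  d0 <- wilcoxon_signed(c(1, 2, 3), c(1, 2, 3))
  expect_equal(d0$p_value, 1)
  expect_match(d0$note, "zero")
})

test_that("Wilcoxon detects a shift better than it rejects the null", {
  set.seed(60)
  reps <- 200; n <- 15
  null_rej <- mean(replicate(reps, {
    x <- rnorm(n); wilcoxon_signed(x, rnorm(n))$p_value < 0.05
  }))
  shift_rej <- mean(replicate(reps, {
    x <- rnorm(n); wilcoxon_signed(x + 1, rnorm(n))$p_value < 0.05
  }))
  expect_lt(null_rej, 0.12)
  expect_gt(shift_rej, null_rej + 0.3)
})

test_that("wilcoxon_by_group runs per sequence and guards small subgroups", {
  set.seed(61)
  d <- make_crossover(n = 12, carryover = -2)
  res <- wilcoxon_by_group(d, c("week0", "week8"))
  expect_named(res, c("A-B", "B-A"))
  expect_s3_class(res[["A-B"]], "test_result")
  tiny <- d[c(1, 2, 3), ]  # only one B-A subject
  expect_error(wilcoxon_by_group(crossover_dataset(tiny)),
               class = "cervgame_validation_error")
})

test_that("residual effect: null construction is calm, carryover is caught", {
  set.seed(62)
  rej_null <- mean(replicate(150, {
    residual_effect(make_crossover(n = 13, carryover = 0))$p_value < 0.05
  }))
  expect_lt(rej_null, 0.12)

  hits <- mean(replicate(150, {
    residual_effect(make_crossover(n = 13, carryover = -2))$p_value < 0.05
  }))
  expect_gt(hits, 0.8)  # -2 shift at n = 13 is found most of the time
  # significant residual escalates to per-sequence Wilcoxon
  set.seed(63)
  r <- residual_effect(make_crossover(n = 14, carryover = -3))
  expect_false(is.null(r$by_group))
  expect_named(r$by_group, c("A-B", "B-A"))
})

test_that("single-subject or incomplete data are refused", {
  d1 <- data.frame(subject = "P1", sequence = "A-B", week0 = 5, week4 = 4,
                   week8 = 5, week12 = 4, week16 = 4)
  expect_error(residual_effect(crossover_dataset(d1)),
               class = "cervgame_validation_error")
  d2 <- data.frame(subject = c("P1", "P2"), sequence = c("A-B", "B-A"),
                   week0 = c(5, 6), week4 = c(4, 5), week8 = c(5, NA),
                   week12 = c(4, 5), week16 = c(4, 5))
  expect_error(crossover_dataset(d2), class = "cervgame_validation_error")
})

test_that("period effect recovers a pure period shift", {
  set.seed(64)
  d <- make_crossover(n = 100, period = -1)
  r <- period_effect(d)
  expect_equal(r$effect, 1, tolerance = 0.35)  # week4 - week12 = -period
  same <- make_crossover(n = 10)
  same$week12 <- same$week4
  r0 <- period_effect(same)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
})

test_that("sequence effect separates constructed A-B vs B-A changes", {
  set.seed(65)
  n <- 40
  seqs <- rep(c("A-B", "B-A"), each = n / 2)
  base <- rnorm(n, 5, 0.3)
  # treatment-A change is -0.5 in the A-B arm, -1.5 in the B-A arm
  w4 <- base + ifelse(seqs == "A-B", -0.5, 0) + rnorm(n, 0, 0.1)
  w8 <- base + rnorm(n, 0, 0.1)
  w12 <- w8 + ifelse(seqs == "B-A", -1.5, 0) + rnorm(n, 0, 0.1)
  d <- crossover_dataset(data.frame(subject = seq_len(n), sequence = seqs,
                                    week0 = base, week4 = w4, week8 = w8,
                                    week12 = w12, week16 = w12))
  r <- sequence_effect(d, "A")
  expect_lt(r$p_value, 0.01)
  expect_equal(r$effect, 1, tolerance = 0.15)   # (-0.5) - (-1.5)
  gm <- r$group_means
  expect_equal(gm$mean_change[gm$sequence == "B-A"], -1.5, tolerance = 0.1)
  expect_error(sequence_effect(d, "C"), class = "cervgame_validation_error")
})

test_that("sequence effect is calm under identical change distributions", {
  set.seed(66)
  rej <- mean(replicate(150, {
    sequence_effect(make_crossover(n = 14, effect_a = -1, effect_b = -1), "A")$p_value < 0.05
  }))
  expect_lt(rej, 0.12)
})

test_that("repeated-measures ANOVA agrees with the sums-of-squares oracle", {
  set.seed(67)
  for (n in 3:5) for (k in 3:5) {
    m <- matrix(rnorm(n * k, mean = 70, sd = 10), n, k)
    expect_equal(rm_anova_sessions(m)$statistic, rm_anova_oracle(m),
                 tolerance = 1e-9)
  }
  # constant rows: no session effect at all
  flat <- matrix(rep(c(60, 70, 80), times = 4), 4, 3, byrow = TRUE)
  expect_lt(abs(rm_anova_sessions(t(flat))$statistic), 1e-9)
})

test_that("rm-ANOVA finds the simulated learning effect", {
  set.seed(68)
  cfg <- game_config(targets_per_series = 7, n_series = 1)
  hits <- mean(replicate(20, {
    scores <- t(replicate(13, simulate_protocol(user_model(), cfg,
                                                n_sessions = 8, rate = 25)))
    rm_anova_sessions(scores)$p_value < 0.05
  }))
  expect_gte(hits, 0.8)
})

test_that("rm-ANOVA refuses incomplete matrices", {
  m <- matrix(rnorm(12), 4, 3); m[2, 2] <- NA
  expect_error(rm_anova_sessions(m), class = "cervgame_validation_error")
  expect_error(rm_anova_sessions(matrix(1, 1, 3)), class = "cervgame_validation_error")
})

test_that("normality gate annotates Gaussian and skewed samples sensibly", {
  set.seed(69)
  rej_gauss <- mean(replicate(200, normality_gate(rnorm(30))$p_value < 0.05))
  expect_lt(rej_gauss, 0.12)
  skew <- normality_gate(rexp(50, rate = 1))
  expect_lt(skew$p_value, 0.05)
  expect_error(normality_gate(c(1, 2)), class = "cervgame_validation_error")
})

test_that("the full crossover report assembles every analysis", {
  set.seed(70)
  d <- make_crossover(n = 13, effect_a = -1.2, effect_b = -1.5)
  scores <- t(replicate(13, 70 + cumsum(rnorm(8, 2, 3))))
  rep_ <- analyze_crossover(d, session_scores = scores)
  expect_s3_class(rep_, "crossover_report")
  for (nm in c("within_treatment_A", "within_treatment_B", "residual",
               "period", "sequence_A", "sequence_B", "rm_anova_sessions",
               "normality_baseline"))
    expect_s3_class(rep_[[nm]], "test_result")
  path <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep_, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$n, 13)
  expect_true(is.numeric(back$period$p_value))
})
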