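# Crossover (AB/BA) trial analysis: paired comparisons, the design-specific
# residual / period / sequence effect checks, Wilcoxon signed-rank by group,
# repeated-measures ANOVA over session scores, and a Shapiro-Wilk
# normality annotation. All tests are two-sided at alpha = .05.

WEEK_COLUMNS <- c("week0", "week4", "week8", "week12", "week16")

#' Crossover trial dataset
#'
#' One row per subject: identifier, treatment sequence (`"A-B"` = serious
#' game first, `"B-A"` = conventional exercise first) and the outcome at the
#' five assessment points: baseline (week 0), after the first intervention
#' (week 4), after the washout (week 8), after the second intervention
#' (week 12) and at follow-up (week 16).
#'
#' @param df a data frame with columns
#'   `subject, sequence, week0, week4, week8, week12, week16`.
#' @return a validated data frame of class `crossover_dataset`.
#' @export
crossover_dataset <- function(df) {
  need <- c("subject", "sequence", WEEK_COLUMNS)
  if (!all(need %in% names(df)))
    abort_validation("crossover data needs columns ", paste(need, collapse = ","))
  if (anyDuplicated(df$subject))
    abort_validation("one row per subject required (duplicated subject ids)")
  if (!all(df$sequence %in% c("A-B", "B-A")))
    abort_validation('sequence must be "A-B" or "B-A"')
  if (any(!is.finite(as.matrix(df[WEEK_COLUMNS]))))
    abort_validation("missing or non-numeric outcome values; completers-only analysis refuses to impute")
  df <- df[, need]
  class(df) <- c("crossover_dataset", "data.frame")
  df
}

#' Read a crossover dataset from CSV
#'
#' Dialect: `subject,sequence,week0,week4,week8,week12,week16`.
#' @param path CSV file path.
#' @return a [crossover_dataset()].
#' @export
read_crossover_csv <- function(path) {
  if (!file.exists(path)) abort_validation("crossover file not found: ", path)
  crossover_dataset(read.csv(path, stringsAsFactors = FALSE))
}

#' Test result container
#'
#' @param method character label of the test.
#' @param statistic test statistic value.
#' @param p_value two-sided p-value.
#' @param n sample size (pairs or subjects).
#' @param effect mean effect (e.g. mean difference), if applicable.
#' @param effect_sd SD of the effect, if applicable.
#' @param df degrees of freedom (scalar or length-2 for F).
#' @param note free-text annotation (degenerate cases etc.).
#' @return an object of class `test_result`.
#' @export
test_result <- function(method, statistic, p_value, n, effect = NA_real_,
                        effect_sd = NA_real_, df = NA_real_, note = NULL) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    abort_validation("p_value must lie in [0, 1]")
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 n = n, effect = effect, effect_sd = effect_sd, df = df,
                 note = note),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %s, p = %s, n = %d\n",
              x$method,
              if (is.na(x$statistic[1])) "NA" else sprintf("%.4f", x$statistic[1]),
              if (is.na(x$p_value)) "NA" else format.pval(x$p_value, digits = 4),
              x$n))
  if (!is.na(x$effect))
    cat(sprintf("  effect (mean difference) = %.4f (SD %.4f)\n", x$effect, x$effect_sd))
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Paired Student t test
#'
#' Two-sided t test for related measures; the effect is the mean of the
#' paired differences `x - y` with its SD.
#'
#' @param x,y numeric vectors of equal length (>= 2 pairs), no missing
#'   values.
#' @return a [test_result()].
#' @export
paired_t <- function(x, y) {
  check_pairs(x, y)
  d <- x - y
  if (sd(d) == 0) {
    if (all(d == 0))
      return(test_result("paired t", 0, 1, length(d), 0, 0, length(d) - 1,
                         note = "all differences zero"))
    abort_validation("zero variance of non-zero differences; paired t undefined")
  }
  tt <- t.test(x, y, paired = TRUE)
  test_result("paired t", unname(tt$statistic), tt$p.value, length(d),
              mean(d), sd(d), unname(tt$parameter))
}

check_pairs <- function(x, y) {
  if (length(x) != length(y))
    abort_validation("paired samples must have equal length")
  if (length(x) < 2L) abort_validation("need at least 2 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    abort_validation("missing values in paired samples; refusing to impute")
  invisible(NULL)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Reports `V`, the sum of the ranks of the positive differences (zeros
#' dropped, standard signed-rank convention). The p-value is exact for 25 or
#' fewer nonzero differences without ties, and a normal approximation with
#' continuity correction otherwise. If every difference is zero the
#' degenerate case is reported with p = 1 and no rejection.
#'
#' @param x,y numeric vectors of equal length.
#' @return a [test_result()].
#' @export
wilcoxon_signed <- function(x, y) {
  check_pairs(x, y)
  d <- x - y
  nz <- d[d != 0]
  if (length(nz) == 0L)
    return(test_result("Wilcoxon signed-rank", NA_real_, 1, length(d), 0, 0,
                       note = "all differences zero; no evidence of change"))
  use_exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
  wt <- suppressWarnings(
    wilcox.test(x, y, paired = TRUE, exact = use_exact, correct = TRUE))
  test_result("Wilcoxon signed-rank", unname(wt$statistic), wt$p.value,
              length(d), mean(d), sd(d),
              note = if (use_exact) "exact p" else "normal approximation")
}

#' Wilcoxon signed-rank comparisons within each sequence group
#'
#' Repeats a paired comparison (two assessment weeks) separately for the
#' A-B and B-A sequence groups — the escalation used to attribute a residual
#' effect to one intervention.
#'
#' @param data a [crossover_dataset()].
#' @param weeks character 2-vector naming the paired assessment columns,
#'   e.g. `c("week0", "week8")`.
#' @return a named list of [test_result()], one per sequence group.
#' @export
wilcoxon_by_group <- function(data, weeks = c("week0", "week8")) {
  data <- as_crossover(data)
  if (!all(weeks %in% WEEK_COLUMNS) || length(weeks) != 2L)
    abort_validation("weeks must name two of ", paste(WEEK_COLUMNS, collapse = ","))
  groups <- split(data, data$sequence)
  if (length(groups) == 0L) abort_validation("empty dataset")
  lapply(groups, function(g) {
    if (nrow(g) < 2L)
      abort_validation("subgroup '", unique(g$sequence), "' has fewer than 2 subjects")
    wilcoxon_signed(g[[weeks[1]]], g[[weeks[2]]])
  })
}

as_crossover <- function(data) {
  if (!inherits(data, "crossover_dataset")) crossover_dataset(data) else data
}

#' Residual (carryover) effect analysis
#'
#' Compares baseline (week 0) with the post-washout assessment (week 8)
#' with a paired t test: a persistent difference means the first-period
#' intervention carried over through the washout. When the test is
#' significant at `alpha`, the comparison is repeated within each sequence
#' group with the Wilcoxon signed-rank test to attribute the carryover to
#' one intervention.
#'
#' @param data a [crossover_dataset()].
#' @param alpha significance level for the escalation (default .05).
#' @return a [test_result()]; when significant it carries a `by_group` list
#'   of per-sequence Wilcoxon results.
#' @export
residual_effect <- function(data, alpha = 0.05) {
  data <- as_crossover(data)
  res <- paired_t(data$week0, data$week8)
  res$method <- "residual effect (paired t, week 0 vs week 8)"
  if (!is.na(res$p_value) && res$p_value < alpha)
    res$by_group <- wilcoxon_by_group(data, c("week0", "week8"))
  res
}

#' Period effect analysis
#'
#' Paired t test comparing the outcome after the first intervention
#' (week 4) with the outcome after the second (week 12), pooled over
#' sequences: a difference indicates that *when* a treatment was given
#' mattered.
#'
#' @param data a [crossover_dataset()].
#' @return a [test_result()].
#' @export
period_effect <- function(data) {
  data <- as_crossover(data)
  res <- paired_t(data$week4, data$week12)
  res$method <- "period effect (paired t, week 4 vs week 12)"
  res
}

#' Sequence effect analysis for one treatment
#'
#' For the named treatment, computes each subject's within-treatment change
#' (post minus pre of the period in which that subject received it: periods
#' run weeks 0-4 and 8-12 according to the sequence) and compares the A-B
#' and B-A groups with a two-sample Student t test (equal variances). Under
#' no sequence effect the change produced by a treatment is the same
#' whichever period it was delivered in.
#'
#' @param data a [crossover_dataset()].
#' @param treatment `"A"` (serious game) or `"B"` (conventional exercise).
#' @return a [test_result()]; `effect` is the difference of group mean
#'   changes (A-B minus B-A), and `group_means` holds the per-sequence mean
#'   changes with SDs.
#' @export
sequence_effect <- function(data, treatment = c("A", "B")) {
  if (!is.character(treatment) || !treatment[1] %in% c("A", "B"))
    abort_validation('treatment must be "A" or "B"')
  treatment <- match.arg(treatment)
  data <- as_crossover(data)
  # change = post - pre for the period in which this subject got `treatment`
  first_period <- (treatment == "A") == (data$sequence == "A-B")
  change <- ifelse(first_period, data$week4 - data$week0,
                   data$week12 - data$week8)
  g_ab <- change[data$sequence == "A-B"]
  g_ba <- change[data$sequence == "B-A"]
  if (length(g_ab) == 0L || length(g_ba) == 0L)
    abort_validation("both sequences must be represented")
  if (length(g_ab) < 2L || length(g_ba) < 2L)
    abort_validation("each sequence group needs at least 2 subjects")
  tt <- t.test(g_ab, g_ba, var.equal = TRUE)
  res <- test_result(
    sprintf("sequence effect, treatment %s (two-sample t on changes)", treatment),
    unname(tt$statistic), tt$p.value, length(change),
    mean(g_ab) - mean(g_ba), NA_real_, unname(tt$parameter))
  res$group_means <- data.frame(
    sequence = c("A-B", "B-A"),
    mean_change = c(mean(g_ab), mean(g_ba)),
    sd_change = c(sd(g_ab), sd(g_ba)),
    n = c(length(g_ab), length(g_ba)))
  res
}

#' One-way repeated-measures ANOVA over session scores
#'
#' Tests whether performance changes across sessions, with subject as the
#' repeated unit: `aov(score ~ session + Error(subject))`, complete matrix
#' required (no imputation).
#'
#' @param scores a numeric matrix, subjects in rows, sessions in columns.
#' @return a [test_result()] with the session-factor F statistic, its
#'   `c(df1, df2)` degrees of freedom and the p-value.
#' @export
rm_anova_sessions <- function(scores) {
  scores <- as.matrix(scores)
  if (any(!is.finite(scores)))
    abort_validation("session score matrix has missing cells; refusing to impute")
  if (nrow(scores) < 2L || ncol(scores) < 2L)
    abort_validation("need at least 2 subjects and 2 sessions")
  long <- data.frame(
    score = as.vector(scores),
    subject = factor(rep(seq_len(nrow(scores)), times = ncol(scores))),
    session = factor(rep(seq_len(ncol(scores)), each = nrow(scores))))
  fit <- aov(score ~ session + Error(subject), data = long)
  tab <- summary(fit)[["Error: Within"]][[1]]
  # degenerate case: no variation across sessions at all (0/0 F)
  scale_ss <- sum(tab[, "Sum Sq"]) + sum((rowMeans(scores) - mean(scores))^2)
  if (tab["session", "Sum Sq"] <= 1e-12 * max(scale_ss, 1))
    return(test_result("repeated-measures ANOVA (session factor)", 0, 1,
                       nrow(scores),
                       df = c(tab["session", "Df"], tab["Residuals", "Df"]),
                       note = "no variation across sessions"))
  test_result("repeated-measures ANOVA (session factor)",
              tab["session", "F value"], tab["session", "Pr(>F)"], nrow(scores),
              df = c(tab["session", "Df"], tab["Residuals", "Df"]))
}

#' Shapiro-Wilk normality annotation
#'
#' Used to annotate whether an outcome looks normally distributed; it does
#' not switch tests automatically.
#'
#' @param values numeric vector, n >= 3.
#' @return a [test_result()] with W and the p-value.
#' @export
normality_gate <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3L)
    abort_validation("Shapiro-Wilk needs at least 3 observations")
  sw <- shapiro.test(values)
  test_result("Shapiro-Wilk", unname(sw$statistic), sw$p.value, length(values))
}

#' Full crossover analysis report
#'
#' Runs the complete analysis battery on one outcome: within-treatment
#' paired comparisons (pre vs post for each treatment, pooled over the
#' period it was received in), the residual, period and both sequence
#' effect analyses, and Shapiro-Wilk annotations of baseline and changes.
#' Optionally adds the repeated-measures ANOVA over a session-score matrix.
#'
#' @param data a [crossover_dataset()].
#' @param session_scores optional subjects x sessions score matrix for
#'   [rm_anova_sessions()].
#' @return a list of class `crossover_report`.
#' @export
analyze_crossover <- function(data, session_scores = NULL) {
  data <- as_crossover(data)
  pre_a <- ifelse(data$sequence == "A-B", data$week0, data$week8)
  post_a <- ifelse(data$sequence == "A-B", data$week4, data$week12)
  pre_b <- ifelse(data$sequence == "B-A", data$week0, data$week8)
  post_b <- ifelse(data$sequence == "B-A", data$week4, data$week12)
  within_a <- paired_t(pre_a, post_a)
  within_a$method <- "within treatment A (paired t, pre vs post)"
  within_b <- paired_t(pre_b, post_b)
  within_b$method <- "within treatment B (paired t, pre vs post)"
  report <- list(
    n = nrow(data),
    normality_baseline = normality_gate(data$week0),
    within_treatment_A = within_a,
    within_treatment_B = within_b,
    residual = residual_effect(data),
    period = period_effect(data),
    sequence_A = sequence_effect(data, "A"),
    sequence_B = sequence_effect(data, "B"))
  if (!is.null(session_scores))
    report$rm_anova_sessions <- rm_anova_sessions(session_scores)
  class(report) <- "crossover_report"
  report
}

#' @export
print.crossover_report <- function(x, ...) {
  cat(sprintf("<crossover_report> n = %d subjects\n", x$n))
  for (nm in setdiff(names(x), "n")) {
    r <- x[[nm]]
    if (inherits(r, "test_result"))
      cat(sprintf("  %-20s p = %s\n", nm, format.pval(r$p_value, digits = 3)))
  }
  invisible(x)
}

#' Write a crossover report as JSON
#'
#' @param report a `crossover_report` from [analyze_crossover()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  strip <- function(r) {
    if (inherits(r, "test_result")) {
      out <- unclass(r)
      out$by_group <- if (!is.null(r$by_group)) lapply(r$by_group, strip)
      out[!vapply(out, is.null, logical(1))]
    } else r
  }
  payload <- lapply(unclass(report), function(el)
    if (inherits(el, "test_result")) strip(el) else el)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}
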