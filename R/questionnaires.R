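# Scorers for the study instruments: SEQ (suitability of virtual
# rehabilitation), NDI (neck disability), MMSE (cognitive screening), and
# range validation for VAS pain ratings.

SEQ_REVERSED <- c(7L, 8L, 9L, 10L, 12L, 13L)

#' Score the Suitability Evaluation Questionnaire (SEQ)
#'
#' Thirteen Likert items rated 1-5. Items Q1-Q6 and Q11 are positively
#' keyed; Q7-Q10, Q12 and Q13 are negatively keyed (discomfort, dizziness,
#' eye strain, disorientation, task and device difficulty) and are reversed
#' with the standard Likert flip `6 - raw` before summing. The total ranges
#' from 13 (worst) to 65 (best). A 14th open-ended comment item exists on
#' the instrument but is never scored.
#'
#' @param items integer vector of the 13 scored responses (Q1-Q13), each in
#'   1..5.
#' @return the total score, an integer in \[13, 65\].
#' @examples
#' score_seq(c(rep(5, 6), rep(1, 4), 5, 1, 1))  # best possible sheet: 65
#' @export
score_seq <- function(items) {
  items <- check_items(items, n = 13L, lo = 1L, hi = 5L, what = "SEQ")
  keyed <- items
  keyed[SEQ_REVERSED] <- 6L - items[SEQ_REVERSED]
  sum(keyed)
}

#' Score the Neck Disability Index (NDI)
#'
#' Ten items (pain intensity, self-care, lifting, reading, headache,
#' concentration, work, driving, sleep, leisure), each 0-5. The raw total is
#' out of 50 and is also expressed as a percentage of the maximum.
#'
#' @param items integer vector of the 10 responses, each in 0..5.
#' @return a list with `raw` (0-50) and `percent` (0-100).
#' @examples
#' score_ndi(rep(5, 10))  # raw 50, 100%
#' @export
score_ndi <- function(items) {
  items <- check_items(items, n = 10L, lo = 0L, hi = 5L, what = "NDI")
  raw <- sum(items)
  list(raw = raw, percent = 100 * raw / 50)
}

check_items <- function(items, n, lo, hi, what) {
  items <- as.numeric(items)
  if (length(items) != n)
    abort_validation(sprintf("%s sheet must have exactly %d items, got %d",
                             what, n, length(items)))
  if (any(!is.finite(items)) || any(items != round(items)) ||
      any(items < lo) || any(items > hi))
    abort_validation(sprintf("%s items must be integers in %d..%d", what, lo, hi))
  as.integer(items)
}

#' Classify an MMSE record
#'
#' Uses the adapted 35-point scale. Severity brackets: 30-35 normal, 24-29
#' borderline, 19-23 mild, 14-18 moderate, below 14 severe. The screening
#' cutoff is age-dependent: 24 points for respondents 65 or older, 29 for
#' younger adults. The optional education adjustment mirrors the
#' error-allowance convention (one extra error tolerated at elementary
#' education, one fewer at university level) by shifting the score used for
#' the cutoff comparison by +/-1; it is off by default and never changes
#' the reported bracket.
#'
#' @param score MMSE score in \[0, 35\].
#' @param age respondent age in years.
#' @param education one of `"standard"`, `"elementary"`, `"university"`.
#' @param education_adjust apply the +/-1 education allowance to the cutoff
#'   comparison (default `FALSE`).
#' @return a list with `bracket`, `cutoff` and `below_cutoff`.
#' @examples
#' mmse_classify(31, age = 82)  # normal, cutoff 24
#' @export
mmse_classify <- function(score, age,
                          education = c("standard", "elementary", "university"),
                          education_adjust = FALSE) {
  education <- match.arg(education)
  if (!is.numeric(score) || length(score) != 1L || score < 0 || score > 35)
    abort_validation("MMSE score must be a single value in [0, 35]")
  if (!is.numeric(age) || length(age) != 1L || age < 0)
    abort_validation("age must be a single non-negative number")
  bracket <- if (score >= 30) "normal"
             else if (score >= 24) "borderline"
             else if (score >= 19) "mild"
             else if (score >= 14) "moderate"
             else "severe"
  cutoff <- if (age >= 65) 24 else 29
  eff <- score
  if (education_adjust) {
    if (education == "elementary") eff <- score + 1
    if (education == "university") eff <- score - 1
  }
  list(bracket = bracket, cutoff = cutoff, below_cutoff = eff < cutoff)
}

#' Validate VAS pain ratings
#'
#' Accepts Visual Analog Scale values in \[0, 10\] and flags poor pain
#' control (a rating strictly above 3 points). Values are stored as-is; no
#' transformation is applied.
#'
#' @param v numeric vector of VAS ratings.
#' @return a data frame with columns `value` and `poor_control`.
#' @examples
#' validate_vas(c(0, 4.9))
#' @export
validate_vas <- function(v) {
  v <- as.numeric(v)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 10))
    abort_validation("VAS values must lie in [0, 10]")
  data.frame(value = v, poor_control = v > 3)
}

#' Read a questionnaire response CSV
#'
#' One row per respondent. Columns: `subject,instrument,item1..itemN`
#' (N = 13 for SEQ, 10 for NDI); MMSE rows instead carry
#' `subject,instrument,score,age,education`.
#'
#' @param path CSV file path.
#' @return a data frame with the file's columns.
#' @export
read_questionnaires <- function(path) {
  if (!file.exists(path)) abort_validation("questionnaire file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject", "instrument") %in% names(df)))
    abort_validation("questionnaire CSV needs columns subject, instrument")
  df
}

#' Score every sheet in a questionnaire table
#'
#' Applies the matching scorer to each row of a [read_questionnaires()]
#' table (instruments `SEQ`, `NDI`, `MMSE`, `VAS`).
#'
#' @param df a questionnaire table.
#' @return a data frame with columns `subject, instrument, score` plus
#'   instrument-specific extras (`percent` for NDI; `bracket`, `cutoff`,
#'   `below_cutoff` for MMSE; `poor_control` for VAS).
#' @export
score_questionnaires <- function(df) {
  rows <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    inst <- toupper(row$instrument)
    base <- data.frame(subject = row$subject, instrument = inst,
                       score = NA_real_, percent = NA_real_,
                       bracket = NA_character_, cutoff = NA_real_,
                       below_cutoff = NA, poor_control = NA)
    if (inst == "SEQ") {
      base$score <- score_seq(as.numeric(row[paste0("item", 1:13)]))
    } else if (inst == "NDI") {
      s <- score_ndi(as.numeric(row[paste0("item", 1:10)]))
      base$score <- s$raw; base$percent <- s$percent
    } else if (inst == "MMSE") {
      cls <- mmse_classify(row$score, row$age,
                           if (is.null(row$education) || is.na(row$education))
                             "standard" else row$education)
      base$score <- row$score; base$bracket <- cls$bracket
      base$cutoff <- cls$cutoff; base$below_cutoff <- cls$below_cutoff
    } else if (inst == "VAS") {
      v <- validate_vas(row$score)
      base$score <- v$value; base$poor_control <- v$poor_control
    } else {
      abort_validation("unknown instrument: ", row$instrument)
    }
    base
  })
  do.call(rbind, rows)
}
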