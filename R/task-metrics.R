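#' Stroop RT interference for one condition
#'
#' Mean reaction time of incongruent trials minus mean reaction time of
#' congruent trials. Positive values mean slower responding under
#' incongruent color-word pairings (the classic interference cost). Trials
#' with missing RT (responses censored at the deadline) are excluded.
#'
#' @param trials Data frame with columns `congruency`
#'   (`"congruent"`/`"incongruent"`) and `rt_ms`; other columns are ignored.
#' @param correct_only Restrict RT means to correct trials.
#' @return Interference in ms.
#' @export
rt_interference <- function(trials, correct_only = FALSE) {
  stopifnot(is.data.frame(trials), all(c("congruency", "rt_ms") %in% names(trials)))
  if (correct_only) trials <- trials[trials$correct %in% TRUE, , drop = FALSE]
  inc <- trials$rt_ms[trials$congruency == "incongruent"]
  con <- trials$rt_ms[trials$congruency == "congruent"]
  inc <- inc[!is.na(inc)]; con <- con[!is.na(con)]
  if (length(inc) < 1 || length(con) < 1) {
    stop("need at least one valid RT per congruency cell")
  }
  mean(inc) - mean(con)
}

#' Stroop accuracy interference for one condition
#'
#' Proportion correct on incongruent trials minus proportion correct on
#' congruent trials; bounded in \eqn{[-1, 1]} and typically slightly
#' negative.
#'
#' @param trials Data frame with columns `congruency` and `correct`.
#' @return Proportion difference.
#' @export
accuracy_interference <- function(trials) {
  stopifnot(is.data.frame(trials), all(c("congruency", "correct") %in% names(trials)))
  inc <- trials$correct[trials$congruency == "incongruent"]
  con <- trials$correct[trials$congruency == "congruent"]
  if (length(inc) < 1 || length(con) < 1) {
    stop("need at least one trial per congruency cell")
  }
  mean(inc) - mean(con)
}

#' Reactivity score
#'
#' Task-segment value minus its immediately preceding baseline-segment value
#' (task - baseline), applied identically to RMSSD (ms) and to HF-peak (Hz).
#' Positive values indicate an increase during the task.
#'
#' @param task_value,baseline_value Scalar segment metrics in the same units.
#' @return `task_value - baseline_value`.
#' @export
reactivity_score <- function(task_value, baseline_value) {
  if (is.na(task_value) || is.na(baseline_value)) {
    stop("missing segment value; cannot compute reactivity")
  }
  task_value - baseline_value
}

#' Intraindividual-variability summary of four condition scores
#'
#' The mean and standard deviation of a subject's four condition-level
#' scores. The SD across conditions is the package's intraindividual
#' variability (IIV) metric: applied to RMSSD reactivity scores it is the
#' vagal flexibility index (Reactivity SD), applied to interference scores
#' it is the (inverse) performance-stability index (Interference SD).
#'
#' @param scores Numeric vector of exactly four condition-level scores.
#' @param denominator `"n-1"` (sample SD, default) or `"n"` (population SD).
#' @return List with `mean` and `sd`.
#' @export
iiv_summary <- function(scores, denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  scores <- as.numeric(scores)
  if (length(scores) != 4 || anyNA(scores)) {
    stop("need exactly 4 non-missing condition scores")
  }
  s <- stats::sd(scores)
  if (denominator == "n") s <- s * sqrt(3 / 4)
  list(mean = mean(scores), sd = s)
}

#' Exclude extreme outliers on named variables
#'
#' Single-pass rule: for each listed variable, subjects whose value deviates
#' from the full-sample mean by strictly more than `k_sd` standard
#' deviations are removed. Means and SDs are computed once on the full
#' sample (not iteratively re-estimated), and a value at exactly `k_sd` SD
#' is retained.
#'
#' @param profiles Data frame of per-subject profiles (needs a `subject`
#'   column).
#' @param variables Character vector of column names to screen.
#' @param k_sd Exclusion threshold in SD units.
#' @return List with `profiles` (filtered) and `exclusions`, a data frame
#'   logging subject, variable, and z-score for each removal.
#' @export
exclude_outliers <- function(profiles, variables, k_sd = 3) {
  stopifnot(is.data.frame(profiles), nrow(profiles) >= 5)
  missing_vars <- setdiff(variables, names(profiles))
  if (length(missing_vars)) {
    stop("variable(s) absent from profiles: ", paste(missing_vars, collapse = ", "))
  }
  logs <- list()
  drop <- rep(FALSE, nrow(profiles))
  for (v in variables) {
    z <- (profiles[[v]] - mean(profiles[[v]])) / stats::sd(profiles[[v]])
    hit <- abs(z) > k_sd
    if (any(hit)) {
      logs[[v]] <- data.frame(subject = profiles$subject[hit], variable = v,
                              z = z[hit], stringsAsFactors = FALSE)
      drop <- drop | hit
    }
  }
  exclusions <- if (length(logs)) do.call(rbind, c(logs, make.row.names = FALSE)) else
    data.frame(subject = character(), variable = character(), z = numeric())
  list(profiles = profiles[!drop, , drop = FALSE], exclusions = exclusions)
}

#' Tertile split
#'
#' Rank-based split into low / medium / high groups at the 1/3 and 2/3
#' cutoffs. Ties are broken by stable (first-occurrence) rank order, and
#' group sizes differ by at most one: the low and high groups each take
#' `round(n/3)` subjects and the medium group the remainder.
#'
#' @param values Numeric vector.
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
tertile_split <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3) stop("need at least 3 subjects for a tertile split")
  if (length(unique(values)) < 3) stop("fewer than 3 distinct values; no split possible")
  r <- rank(values, ties.method = "first")
  k <- round(n / 3)
  lab <- ifelse(r <= k, "low", ifelse(r > n - k, "high", "medium"))
  factor(lab, levels = c("low", "medium", "high"))
}
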