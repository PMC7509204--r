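#' Build per-subject profiles from sessions
#'
#' Runs the full measurement pipeline for each subject: artifact
#' correction and RMSSD for all nine segments, AR-spectral HF-peak
#' extraction, per-condition reactivity (task - baseline) and Stroop
#' interference scores, and the four-condition intraindividual-variability
#' summaries. The log of Reactivity SD is floored at 0.01 ms before the log
#' (a zero-spread subject would otherwise produce -Inf); a warning reports
#' any flooring.
#'
#' @param sessions A `vf_cohort` or its `sessions` list (see
#'   [generate_cohort()] / [read_cohort()]).
#' @param artifact_threshold_ms Artifact-correction threshold (ms).
#' @param resample_hz,ar_order Spectral settings, see
#'   [compute_ar_spectrum()].
#' @param spectra `"all"` computes the HF peak for every segment (needed
#'   for the HF-peak reactivity covariates), `"resting"` only for the rest
#'   baseline (sufficient for the mediation covariate set and much
#'   faster), `"none"` skips spectra entirely.
#' @param sd_denominator Passed to [iiv_summary()].
#' @param correct_only Restrict RT means to correct trials.
#' @return Data frame with one row per subject: covariates, resting
#'   RMSSD/lnRMSSD and HF-peak, reactivity mean/SD (and ln SD),
#'   interference mean/SD, accuracy-interference mean, HF-peak reactivity
#'   mean/SD, overall mean RT and accuracy, and artifact counts.
#' @export
build_profiles <- function(sessions, artifact_threshold_ms = 250,
                           resample_hz = 4, ar_order = 16,
                           spectra = c("all", "resting", "none"),
                           sd_denominator = "n-1", correct_only = FALSE) {
  spectra <- match.arg(spectra)
  if (inherits(sessions, "vf_cohort")) sessions <- sessions$sessions
  floored <- character()

  rows <- lapply(sessions, function(ses) {
    seg_metric <- function(seg, want_spectrum) {
      hrv_summary(ses$segments[[seg]], threshold_ms = artifact_threshold_ms,
                  spectrum = want_spectrum, resample_hz = resample_hz,
                  order = ar_order)
    }
    rest <- seg_metric("rest_baseline", spectra %in% c("all", "resting"))
    conds <- vf_conditions()
    react <- hf_react <- interf <- acc_interf <- numeric(4)
    n_corr <- rest$n_corrected
    for (j in seq_along(conds)) {
      b <- seg_metric(paste0(conds[j], "_baseline"), spectra == "all")
      t <- seg_metric(paste0(conds[j], "_task"), spectra == "all")
      n_corr <- n_corr + b$n_corrected + t$n_corrected
      react[j] <- reactivity_score(t$rmssd, b$rmssd)
      hf_react[j] <- if (spectra == "all") {
        reactivity_score(t$hf_peak, b$hf_peak)
      } else NA_real_
      ctr <- ses$trials[ses$trials$condition == conds[j], , drop = FALSE]
      interf[j] <- rt_interference(ctr, correct_only = correct_only)
      acc_interf[j] <- accuracy_interference(ctr)
    }
    r_iiv <- iiv_summary(react, denominator = sd_denominator)
    i_iiv <- iiv_summary(interf, denominator = sd_denominator)
    hf_iiv <- if (spectra == "all") iiv_summary(hf_react, denominator = sd_denominator) else
      list(mean = NA_real_, sd = NA_real_)
    sd_for_log <- r_iiv$sd
    if (sd_for_log < 0.01) {
      floored <<- c(floored, ses$subject)
      sd_for_log <- 0.01
    }
    data.frame(
      subject = ses$subject, age = ses$covariates$age, sex = ses$covariates$sex,
      bmi = ses$covariates$bmi,
      resting_rmssd = rest$rmssd, resting_ln_rmssd = rest$ln_rmssd,
      resting_hf_peak = rest$hf_peak, resting_hf_power = rest$hf_power,
      reactivity_mean = r_iiv$mean, reactivity_sd = r_iiv$sd,
      ln_reactivity_sd = log(sd_for_log),
      interference_mean = i_iiv$mean, interference_sd = i_iiv$sd,
      accuracy_interference_mean = mean(acc_interf),
      hf_peak_reactivity_mean = hf_iiv$mean, hf_peak_reactivity_sd = hf_iiv$sd,
      mean_rt = mean(ses$trials$rt_ms, na.rm = TRUE),
      mean_accuracy = mean(ses$trials$correct),
      n_corrected = n_corr, stringsAsFactors = FALSE)
  })
  if (length(floored)) {
    warning("reactivity SD floored at 0.01 ms before log for: ",
            paste(floored, collapse = ", "))
  }
  do.call(rbind, rows)
}

#' Cohort-level skew-transform decisions
#'
#' Applies the Shapiro-Wilk-gated log transform ([ln_skew_transform()]) to
#' each named profile column and records the decisions, mirroring the usual
#' preprocessing step in which positively skewed HRV metrics (resting
#' RMSSD, Reactivity SD) are log transformed before correlational analysis.
#'
#' @param profiles Profile data frame from [build_profiles()].
#' @param variables Columns to screen.
#' @return List with `profiles` (transformed columns renamed `ln_<var>` if
#'   a transform was applied) and `decisions`, a data frame of per-variable
#'   test results.
#' @export
apply_skew_transforms <- function(profiles,
                                  variables = c("resting_rmssd", "reactivity_sd",
                                                "interference_sd")) {
  decisions <- lapply(variables, function(v) {
    res <- ln_skew_transform(profiles[[v]])
    if (res$applied) profiles[[paste0("ln_", v)]] <<- res$values
    data.frame(variable = v, shapiro_p = res$shapiro_p,
               skewness = res$skewness, transformed = res$applied,
               stringsAsFactors = FALSE)
  })
  list(profiles = profiles, decisions = do.call(rbind, decisions))
}
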