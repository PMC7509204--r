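#' Cohort-generation specification
#'
#' Bundles the parameters of the synthetic cohort: the latent mediation
#' chain (standardized paths from resting vagal trait to vagal flexibility
#' to interference stability), the interbeat-interval generator settings,
#' and the Stroop trial generator settings. Defaults emulate the study
#' conditions the pipeline is designed for: 47 analyzable subjects, a
#' strong trait-to-flexibility path, a moderate negative
#' flexibility-to-instability path, and no direct effect (full mediation).
#'
#' @param n_subjects Number of subjects (>= 4).
#' @param path_a Standardized effect of the latent resting-vagal trait on
#'   latent flexibility.
#' @param path_b Standardized effect of latent flexibility on latent
#'   interference instability (negative: more flexibility, more stability).
#' @param path_c_prime Standardized direct effect of the trait on
#'   instability.
#' @param noise_sd_m,noise_sd_y Residual SDs of the latent equations; the
#'   defaults standardize the latent mediator and outcome.
#' @param mean_ibi_ms Cohort-mean interbeat interval (ms).
#' @param rsa_freq_hz Cohort-mean respiratory modulation frequency (Hz),
#'   within the 0.15-0.4 Hz high-frequency band.
#' @param rsa_amp_range_ms Allowed range for the respiratory sinus
#'   arrhythmia amplitude (ms).
#' @param base_rt_ms Ex-Gaussian mu for congruent Stroop RTs (ms).
#' @param rt_sigma_ms,rt_tau_ms Ex-Gaussian sigma and tau (ms).
#' @param interference_ms Population congruency effect on RT (ms).
#' @param emotion_distraction_ms Extra interference under high-emotion
#'   distractors at zero flexibility (ms); scaled down as flexibility rises.
#' @param accuracy_base Probability correct on congruent trials.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 47,
                        path_a = 0.65, path_b = -0.40, path_c_prime = 0,
                        noise_sd_m = sqrt(1 - path_a^2),
                        noise_sd_y = sqrt(max(1 - path_b^2 - path_c_prime^2 -
                                                2 * path_a * path_b * path_c_prime, 0.05)),
                        mean_ibi_ms = 840, rsa_freq_hz = 0.25,
                        rsa_amp_range_ms = c(1, 150),
                        base_rt_ms = 790, rt_sigma_ms = 50, rt_tau_ms = 130,
                        interference_ms = 110, emotion_distraction_ms = 60,
                        accuracy_base = 0.985, seed = 1L) {
  spec <- list(n_subjects = as.integer(n_subjects), path_a = path_a,
               path_b = path_b, path_c_prime = path_c_prime,
               noise_sd_m = noise_sd_m, noise_sd_y = noise_sd_y,
               mean_ibi_ms = mean_ibi_ms, rsa_freq_hz = rsa_freq_hz,
               rsa_amp_range_ms = rsa_amp_range_ms, base_rt_ms = base_rt_ms,
               rt_sigma_ms = rt_sigma_ms, rt_tau_ms = rt_tau_ms,
               interference_ms = interference_ms,
               emotion_distraction_ms = emotion_distraction_ms,
               accuracy_base = accuracy_base, seed = as.integer(seed))
  if (spec$n_subjects < 4) stop("n_subjects must be >= 4")
  if (spec$rsa_freq_hz < 0.15 || spec$rsa_freq_hz > 0.4) {
    stop("rsa_freq_hz must lie in the HF band [0.15, 0.4]")
  }
  if (spec$noise_sd_m < 0 || spec$noise_sd_y < 0 || spec$rt_sigma_ms < 0 ||
      spec$rt_tau_ms < 0) {
    stop("all SD parameters must be nonnegative")
  }
  if (spec$accuracy_base < 0 || spec$accuracy_base > 1) {
    stop("accuracy_base must be a probability")
  }
  if (spec$mean_ibi_ms <= 300 || spec$mean_ibi_ms >= 2000) {
    stop("mean_ibi_ms outside the physiological range (300, 2000)")
  }
  structure(spec, class = "cohort_spec")
}

#' The four socioemotional distractor conditions
#'
#' Low/high emotion crossed with low/high social auditory content.
#' @export
vf_conditions <- function() c("LELS", "HELS", "LEHS", "HEHS")

high_emotion <- function(cond) cond %in% c("HELS", "HEHS")
high_social <- function(cond) cond %in% c("LEHS", "HEHS")

#' Generate a counterbalanced condition order
#'
#' Draws a permutation of the four conditions uniformly from the set of
#' permutations in which the two high-emotion conditions (HELS, HEHS) are
#' never adjacent and the two high-social conditions (LEHS, HEHS) are never
#' adjacent, mirroring the session counterbalancing constraint. Sampling is
#' by rejection, so every valid order is equally likely.
#'
#' @param seed Optional integer seed.
#' @return Character vector of the 4 condition labels in session order.
#' @export
generate_condition_order <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  conds <- vf_conditions()
  repeat {
    ord <- sample(conds)
    adj <- function(a, b) abs(match(a, ord) - match(b, ord)) == 1
    if (!adj("HELS", "HEHS") && !adj("LEHS", "HEHS")) return(ord)
  }
}

#' Generate a synthetic interbeat-interval series
#'
#' Additive model on the interval tachogram: a mean level (plus optional
#' shift), a respiratory sinusoid at `rsa_freq_hz` whose amplitude grows
#' with `vagal_tone`, and AR(1) noise whose scale also grows with
#' `vagal_tone`. Amplitude and noise scale are set so that the expected
#' RMSSD of the series approximately equals `vagal_tone` (in ms), which
#' makes the generator directly steerable by downstream latent traits:
#' `vagal_tone = 0` gives a constant series with RMSSD 0.
#'
#' @param duration_s Segment duration in seconds (> 0).
#' @param mean_ibi_ms Mean interbeat interval (ms), in (300, 2000).
#' @param vagal_tone Target RMSSD of the series (ms, >= 0).
#' @param rsa_freq_hz Respiratory modulation frequency (Hz).
#' @param shift_ms Constant shift added to every interval (ms).
#' @param amp_range_ms Clamp range for the sinusoid amplitude (ms).
#' @param noise_frac Fraction of squared RMSSD contributed by the AR(1)
#'   noise (the rest comes from the respiratory sinusoid).
#' @param ar_phi AR(1) coefficient of the noise.
#' @param seed Optional integer seed.
#' @return An `ibi_series`.
#' @export
generate_ibi_series <- function(duration_s, mean_ibi_ms = 840, vagal_tone = 50,
                                rsa_freq_hz = 0.25, shift_ms = 0,
                                amp_range_ms = c(1, 150), noise_frac = 0.15,
                                ar_phi = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (duration_s <= 0) stop("duration_s must be positive")
  if (mean_ibi_ms <= 300 || mean_ibi_ms >= 2000) {
    stop("mean_ibi_ms outside the physiological range (300, 2000)")
  }
  if (vagal_tone < 0) stop("vagal_tone must be nonnegative")
  level <- mean_ibi_ms + shift_ms
  dt <- level / 1000
  n <- ceiling(duration_s / dt) + 2L

  # successive differences of A*sin(2*pi*f*t) at spacing dt have RMS
  # sqrt(2)*A*|sin(pi*f*dt)|; AR(1) diffs have variance 2*sd_e^2/(1+phi).
  # Split vagal_tone^2 between the two sources so E[RMSSD] ~ vagal_tone.
  sin_fac <- sqrt(2) * abs(sin(pi * rsa_freq_hz * dt))
  amp <- vagal_tone * sqrt(1 - noise_frac) / max(sin_fac, 1e-6)
  if (vagal_tone > 0) amp <- min(max(amp, amp_range_ms[1]), amp_range_ms[2])
  sd_e <- vagal_tone * sqrt(noise_frac * (1 + ar_phi) / 2)

  t_k <- (seq_len(n) - 1) * dt
  phase <- stats::runif(1, 0, 2 * pi)
  rsa <- amp * sin(2 * pi * rsa_freq_hz * t_k + phase)
  noise <- if (sd_e > 0) {
    as.numeric(stats::filter(stats::rnorm(n, sd = sd_e), ar_phi,
                             method = "recursive"))
  } else rep(0, n)
  ibi <- pmax(level + rsa + noise, 250)
  keep <- cumsum(ibi) <= duration_s * 1000
  if (!any(keep)) keep[1] <- TRUE
  ibi_series(ibi[keep])
}

#' Generate Stroop trials for one condition
#'
#' 64 trials (32 congruent, 32 incongruent) with ex-Gaussian reaction
#' times. Incongruent trials are slowed by `interference_ms`; under
#' high-emotion distractor conditions the interference is further inflated
#' by `emotion_distraction_ms * (1 - flexibility_level)`, so highly
#' flexible subjects are less emotionally distractible. Responses slower
#' than the 5 s deadline are censored: RT is recorded as missing and the
#' trial counted incorrect.
#'
#' @param condition One of `"LELS"`, `"HELS"`, `"LEHS"`, `"HEHS"`.
#' @param flexibility_level Scaling in \eqn{[0, 1]}: 0 = fully distractible,
#'   1 = emotion distraction fully suppressed.
#' @param spec A [cohort_spec()].
#' @param interference_extra_ms Additional subject-by-condition interference
#'   offset (ms) on top of the population effects.
#' @param rt_shift_ms Subject-level shift of all RTs (ms).
#' @param n_per_cell Trials per congruency cell.
#' @param seed Optional integer seed.
#' @return Data frame with `condition`, `trial_index`, `congruency`,
#'   `rt_ms` (NA when censored), and `correct`.
#' @export
generate_trials <- function(condition, flexibility_level, spec = cohort_spec(),
                            interference_extra_ms = 0, rt_shift_ms = 0,
                            n_per_cell = 32, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!condition %in% vf_conditions()) {
    stop("invalid condition label: ", condition)
  }
  flexibility_level <- min(max(flexibility_level, 0), 1)
  n <- 2L * n_per_cell
  congruency <- sample(rep(c("congruent", "incongruent"), each = n_per_cell))
  inc <- congruency == "incongruent"
  interference <- spec$interference_ms + interference_extra_ms +
    if (high_emotion(condition)) {
      spec$emotion_distraction_ms * (1 - flexibility_level)
    } else 0
  rt <- spec$base_rt_ms + rt_shift_ms + ifelse(inc, interference, 0) +
    stats::rnorm(n, 0, spec$rt_sigma_ms) + stats::rexp(n, 1 / spec$rt_tau_ms)
  p_correct <- spec$accuracy_base - ifelse(inc, 0.015, 0)
  correct <- stats::runif(n) < p_correct
  censored <- rt > 5000
  rt[censored] <- NA_real_
  correct[censored] <- FALSE
  data.frame(condition = condition, trial_index = seq_len(n),
             congruency = congruency, rt_ms = rt, correct = correct,
             stringsAsFactors = FALSE)
}

# Latent-to-observable mapping constants. These encode the cohort-level
# location/scale of each measured quantity (chosen to emulate a healthy
# young-adult sample) and the slopes that tie the latent traits to them:
#   resting lnRMSSD  = ln_rmssd_mu + ln_rmssd_beta * T
#   ln(reactivity spread) = ln_react_sd_mu + ln_react_sd_beta * F
#   interference spread  = interf_sd_mu + interf_sd_beta * S  (S is the
#     latent instability score: path_b < 0 makes flexible subjects stable)
# The spread patterns d/h are fixed zero-mean unit-SD contrasts over the
# four conditions (assigned by session position), so the SD of a subject's
# four scores recovers the intended spread rather than a chi-distributed
# multiple of it. The interference map is linear so that the measured
# Interference SD stays close to linear in S (the analysis models it
# untransformed).
vf_constants <- function() {
  list(ln_rmssd_mu = 3.88, ln_rmssd_beta = 0.45,
       ln_react_sd_mu = 2.33, ln_react_sd_beta = 0.60,
       react_mean_mu = 1.2, react_mean_sd = 8,
       interf_sd_mu = 100, interf_sd_beta = 45, interf_subject_sd = 70,
       age_mean = 19.5, age_sd = 1.45, p_female = 0.66,
       bmi_mean = 24.1, bmi_sd = 4.2,
       ibi_subject_sd = 120, resp_freq_sd = 0.05, resp_task_shift = 0.035,
       rt_subject_sd = 180,
       rest_s = 300, baseline_s = 120, task_s = 180,
       pattern = c(-3, -1, 1, 3) / stats::sd(c(-3, -1, 1, 3)),
       pattern_interf = c(1, -3, 3, -1) / stats::sd(c(1, -3, 3, -1)))
}

#' Generate a synthetic cohort with known latent mediation structure
#'
#' Draws, per subject, a latent resting-vagal trait `T ~ N(0, 1)`, latent
#' flexibility `F = path_a * T + e_m`, and latent interference instability
#' `S = path_b * F + path_c_prime * T + e_y`, then realizes a full session:
#' a 5 min rest baseline plus, for each of the four socioemotional
#' conditions in a counterbalanced order, a 2 min baseline and a task
#' segment, and 64 Stroop trials per condition. `T` sets the resting vagal
#' tone (hence resting RMSSD), `F` sets the spread of the per-condition
#' vagal reactivity shifts, and `S` — the latent instability score — sets
#' the spread of the per-condition interference offsets (with `path_b < 0`,
#' flexible subjects end up with stable interference). Fully reproducible
#' from `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param spectra_needed Unused placeholder for future fidelity switches.
#' @return A list of class `vf_cohort` with `sessions` (list of per-subject
#'   sessions: `subject`, `covariates`, `condition_order`, `segments` (9
#'   `ibi_series`), `trials`), `truth` (data frame of latent traits,
#'   residuals, and true per-condition shifts), and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec(), spectra_needed = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_subjects < 4) stop("n_subjects must be >= 4 for downstream statistics")
  set.seed(spec$seed)
  k <- vf_constants()
  n <- spec$n_subjects
  ids <- sprintf("S%03d", seq_len(n))

  T_lat <- stats::rnorm(n)
  e_m <- stats::rnorm(n, 0, spec$noise_sd_m)
  e_y <- stats::rnorm(n, 0, spec$noise_sd_y)
  F_lat <- spec$path_a * T_lat + e_m
  S_lat <- spec$path_b * F_lat + spec$path_c_prime * T_lat + e_y

  sessions <- vector("list", n)
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    age <- round(min(max(stats::rnorm(1, k$age_mean, k$age_sd), 18), 26))
    sex <- stats::rbinom(1, 1, k$p_female)
    bmi <- round(min(max(stats::rnorm(1, k$bmi_mean, k$bmi_sd), 17), 40), 1)
    ibi_i <- min(max(stats::rnorm(1, spec$mean_ibi_ms, k$ibi_subject_sd), 600), 1200)
    resp_i <- min(max(stats::rnorm(1, spec$rsa_freq_hz, k$resp_freq_sd), 0.16), 0.38)
    rt_shift <- stats::rnorm(1, 0, k$rt_subject_sd)

    tone_rest <- exp(k$ln_rmssd_mu + k$ln_rmssd_beta * T_lat[i])
    spread_r <- min(max(exp(k$ln_react_sd_mu + k$ln_react_sd_beta * F_lat[i]), 0.5), 90)
    mu_r <- stats::rnorm(1, k$react_mean_mu, k$react_mean_sd)
    spread_i <- min(max(k$interf_sd_mu + k$interf_sd_beta * S_lat[i], 4), 450)
    flex_level <- stats::pnorm(F_lat[i])

    ord <- generate_condition_order()
    react_shift <- mu_r + spread_r * k$pattern          # by session position
    # a stable subject-level interference offset (wide between-subject
    # spread in mean interference) plus the condition pattern scaled by the
    # latent instability; the offset cancels out of the four-condition SD
    subj_interf <- stats::rnorm(1, 0, k$interf_subject_sd)
    interf_extra <- subj_interf + spread_i * k$pattern_interf

    segments <- list(
      rest_baseline = generate_ibi_series(k$rest_s, ibi_i, tone_rest, resp_i,
                                          amp_range_ms = spec$rsa_amp_range_ms)
    )
    trials <- vector("list", 4)
    for (j in seq_along(ord)) {
      cond <- ord[j]
      tone_b <- max(tone_rest * exp(stats::rnorm(1, 0, 0.05)), 3)
      tone_t <- max(tone_b + react_shift[j], 3)
      fb <- min(max(resp_i + stats::rnorm(1, 0, 0.01), 0.155), 0.395)
      ft <- min(max(resp_i + k$resp_task_shift + stats::rnorm(1, 0, 0.01), 0.155), 0.395)
      segments[[paste0(cond, "_baseline")]] <-
        generate_ibi_series(k$baseline_s, ibi_i, tone_b, fb,
                            amp_range_ms = spec$rsa_amp_range_ms)
      segments[[paste0(cond, "_task")]] <-
        generate_ibi_series(k$task_s, ibi_i, tone_t, ft,
                            amp_range_ms = spec$rsa_amp_range_ms)
      trials[[j]] <- generate_trials(cond, flex_level, spec,
                                     interference_extra_ms = interf_extra[j],
                                     rt_shift_ms = rt_shift)
    }
    trials <- do.call(rbind, trials)
    trials <- cbind(subject = ids[i], trials, stringsAsFactors = FALSE)

    sessions[[i]] <- list(subject = ids[i],
                          covariates = list(age = age, sex = sex, bmi = bmi),
                          condition_order = ord,
                          segments = segments, trials = trials)
    truth_rows[[i]] <- data.frame(
      subject = ids[i], T = T_lat[i], F = F_lat[i], S = S_lat[i],
      e_m = e_m[i], e_y = e_y[i], tone_rest = tone_rest,
      spread_react = spread_r, spread_interf = spread_i,
      condition_order = paste(ord, collapse = ","),
      shift1 = react_shift[1], shift2 = react_shift[2],
      shift3 = react_shift[3], shift4 = react_shift[4],
      stringsAsFactors = FALSE)
  }
  structure(list(sessions = sessions,
                 truth = do.call(rbind, truth_rows), spec = spec),
            class = "vf_cohort")
}

#' @export
print.vf_cohort <- function(x, ...) {
  cat(sprintf("<vf_cohort> %d subjects, paths a=%.2f b=%.2f c'=%.2f, seed %d\n",
              length(x$sessions), x$spec$path_a, x$spec$path_b,
              x$spec$path_c_prime, x$spec$seed))
  invisible(x)
}

#' Write a cohort to plain-text files
#'
#' RR files are written one per segment as `<subject>_<segment>.txt`, one
#' interval in ms per line (the common RR text dialect). Trial logs,
#' covariates, and the latent ground truth go to `trials.csv`,
#' `covariates.csv`, and `ground_truth.csv`.
#'
#' @param cohort A `vf_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "vf_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ses in cohort$sessions) {
    for (seg in names(ses$segments)) {
      writeLines(sprintf("%.3f", ses$segments[[seg]]$intervals),
                 file.path(dir, paste0(ses$subject, "_", seg, ".txt")))
    }
  }
  trials <- do.call(rbind, lapply(cohort$sessions, `[[`, "trials"))
  utils::write.csv(trials, file.path(dir, "trials.csv"), row.names = FALSE)
  covs <- do.call(rbind, lapply(cohort$sessions, function(s) {
    data.frame(subject = s$subject, age = s$covariates$age,
               sex = s$covariates$sex, bmi = s$covariates$bmi,
               condition_order = paste(s$condition_order, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(covs, file.path(dir, "covariates.csv"), row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing the RR text files, `trials.csv`, and
#'   `covariates.csv`.
#' @return A list of per-subject sessions in the same shape as
#'   `generate_cohort()$sessions`.
#' @export
read_cohort <- function(dir) {
  covs <- utils::read.csv(file.path(dir, "covariates.csv"),
                          stringsAsFactors = FALSE)
  trials <- utils::read.csv(file.path(dir, "trials.csv"),
                            stringsAsFactors = FALSE)
  seg_names <- c("rest_baseline",
                 as.vector(t(outer(vf_conditions(), c("baseline", "task"),
                                   paste, sep = "_"))))
  lapply(seq_len(nrow(covs)), function(i) {
    id <- covs$subject[i]
    segments <- lapply(seg_names, function(seg) {
      path <- file.path(dir, paste0(id, "_", seg, ".txt"))
      if (!file.exists(path)) stop("missing RR file: ", path)
      ibi_series(as.numeric(readLines(path)), segment = seg, subject = id)
    })
    names(segments) <- seg_names
    list(subject = id,
         covariates = list(age = covs$age[i], sex = covs$sex[i], bmi = covs$bmi[i]),
         condition_order = strsplit(covs$condition_order[i], ",")[[1]],
         segments = segments,
         trials = trials[trials$subject == id, , drop = FALSE])
  })
}
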