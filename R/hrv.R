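#' Interbeat-interval series
#'
#' Lightweight container for an ordered series of interbeat (RR) intervals
#' from one recording segment. All HRV metrics in the package accept either
#' a bare numeric vector of intervals in milliseconds or an `ibi_series`.
#'
#' @param intervals Numeric vector of interbeat intervals in milliseconds.
#' @param segment Optional segment label (e.g. `"rest_baseline"`).
#' @param subject Optional subject identifier.
#' @return An object of class `ibi_series`.
#' @export
ibi_series <- function(intervals, segment = NA_character_, subject = NA_character_) {
  intervals <- as.numeric(intervals)
  if (any(!is.finite(intervals)) || any(intervals <= 0)) {
    stop("all interbeat intervals must be finite and positive (ms)")
  }
  structure(list(intervals = intervals, segment = segment, subject = subject),
            class = "ibi_series")
}

#' @export
print.ibi_series <- function(x, ...) {
  cat(sprintf("<ibi_series> %d intervals, %.1f s total, segment=%s subject=%s\n",
              length(x$intervals), sum(x$intervals) / 1000,
              x$segment, x$subject))
  invisible(x)
}

as_intervals <- function(x) {
  if (inherits(x, "ibi_series")) return(x$intervals)
  as.numeric(x)
}

#' Root mean square of successive differences
#'
#' RMSSD, the standard time-domain index of cardiac vagal activity:
#' `sqrt(mean(diff(ibi)^2))`. It is invariant to adding a constant to all
#' intervals and scales linearly with the intervals.
#'
#' @param series An `ibi_series` or numeric vector of intervals (ms).
#' @return RMSSD in milliseconds.
#' @examples
#' compute_rmssd(c(800, 810, 790, 800)) # sqrt(200)
#' @export
compute_rmssd <- function(series) {
  x <- as_intervals(series)
  if (length(x) < 2) stop("need at least 2 intervals to compute RMSSD")
  sqrt(mean(diff(x)^2))
}

#' Artifact correction for RR series
#'
#' Flags intervals deviating from a centered running-median baseline by more
#' than `threshold_ms` (missed or extra beats, mislabeled R-spikes) and
#' replaces them with cubic-spline interpolated values, in the spirit of the
#' threshold-based correction used by standard HRV software.
#'
#' @param series An `ibi_series` or numeric vector of intervals (ms).
#' @param threshold_ms Deviation threshold from the local median (ms).
#' @param window Running-median window in beats (odd).
#' @return A list with `series` (corrected, same class as input) and
#'   `n_corrected`, the number of replaced intervals.
#' @export
correct_artifacts <- function(series, threshold_ms = 250, window = 11) {
  x <- as_intervals(series)
  n <- length(x)
  if (n < 5) stop("series too short for artifact correction (need >= 5 beats)")
  window <- min(window, if (n %% 2 == 1) n else n - 1)
  baseline <- stats::runmed(x, k = window, endrule = "median")
  bad <- abs(x - baseline) > threshold_ms
  n_bad <- sum(bad)
  if (n_bad > n / 2) {
    stop("more than half of the intervals flagged as artifacts; segment unusable")
  }
  if (n_bad > 0) {
    good <- which(!bad)
    x[bad] <- stats::spline(x = good, y = x[good], xout = which(bad),
                            method = "fmm")$y
    # spline overshoot cannot produce a nonphysiological interval
    x[bad] <- pmax(x[bad], 200)
  }
  out <- if (inherits(series, "ibi_series")) {
    ibi_series(x, segment = series$segment, subject = series$subject)
  } else x
  list(series = out, n_corrected = n_bad)
}

#' Autoregressive spectrum of an IBI series
#'
#' Interpolates the irregularly sampled interval tachogram to an evenly
#' sampled signal (cubic spline), removes a linear trend, fits an AR model by
#' Burg's method, and evaluates the parametric spectral density on a fixed
#' frequency grid. High-frequency (HF) power is the integral of the density
#' over `band` and the HF peak is the frequency of maximal density within the
#' band — the latter serving as a proxy for respiration rate.
#'
#' @param series An `ibi_series` or numeric vector of intervals (ms).
#' @param resample_hz Resampling rate for the evenly sampled tachogram (Hz).
#' @param order AR model order for the Burg fit.
#' @param band HF band limits in Hz.
#' @param grid_step_hz Frequency grid step for density evaluation (Hz).
#' @return An object of class `ar_spectrum`: `freq` (Hz), `power` (ms^2/Hz,
#'   one-sided), `order`, `resample_hz`, `hf_power` (ms^2), `hf_peak` (Hz),
#'   and `signal_var`, the variance of the detrended resampled signal.
#' @export
compute_ar_spectrum <- function(series, resample_hz = 4, order = 16,
                                band = c(0.15, 0.4), grid_step_hz = 0.001) {
  x <- as_intervals(series)
  if (sum(x) / 1000 < 60) {
    stop("segment shorter than 60 s; AR spectral estimate would be unreliable")
  }
  if (stats::sd(x) < 1e-8) stop("constant series: no variance to analyze")
  t_beats <- cumsum(x) / 1000
  grid_t <- seq(t_beats[1], t_beats[length(t_beats)], by = 1 / resample_hz)
  sig <- stats::spline(x = t_beats, y = x, xout = grid_t, method = "fmm")$y
  sig <- stats::lm.fit(cbind(1, grid_t), sig)$residuals
  if (stats::sd(sig) < 1e-8) stop("degenerate signal after detrending")

  fit <- stats::ar.burg(sig, aic = FALSE, order.max = order, demean = TRUE)
  coefs <- fit$ar
  freq <- seq(0, resample_hz / 2, by = grid_step_hz)
  # one-sided AR density: 2 * sigma^2 / fs / |1 - sum_j a_j e^{-i 2 pi f j / fs}|^2
  ej <- exp(-2i * pi * outer(freq / resample_hz, seq_along(coefs)))
  denom <- Mod(1 - as.vector(ej %*% coefs))^2
  power <- 2 * fit$var.pred / resample_hz / denom

  in_band <- freq >= band[1] & freq <= band[2]
  fb <- freq[in_band]; pb <- power[in_band]
  hf_power <- sum((pb[-1] + pb[-length(pb)]) / 2 * diff(fb))
  hf_peak <- fb[which.max(pb)]

  structure(list(freq = freq, power = power, order = order,
                 resample_hz = resample_hz, hf_power = hf_power,
                 hf_peak = hf_peak, signal_var = stats::var(sig)),
            class = "ar_spectrum")
}

#' @export
print.ar_spectrum <- function(x, ...) {
  cat(sprintf("<ar_spectrum> order %d at %g Hz: HF power %.1f ms^2, HF peak %.3f Hz\n",
              x$order, x$resample_hz, x$hf_power, x$hf_peak))
  invisible(x)
}

#' Summarize HRV metrics for one segment
#'
#' Convenience wrapper: artifact correction, RMSSD, and (optionally) the AR
#' spectral HF power and HF peak frequency.
#'
#' @inheritParams compute_ar_spectrum
#' @param threshold_ms Artifact-correction threshold (ms); `NULL` skips
#'   correction.
#' @param spectrum Compute the AR spectrum? Skipping it saves most of the
#'   computation when only RMSSD is needed.
#' @return A list with `rmssd`, `ln_rmssd`, `hf_power`, `hf_peak`,
#'   `n_corrected`.
#' @export
hrv_summary <- function(series, threshold_ms = 250, spectrum = TRUE,
                        resample_hz = 4, order = 16) {
  n_corrected <- 0L
  if (!is.null(threshold_ms)) {
    corr <- correct_artifacts(series, threshold_ms = threshold_ms)
    series <- corr$series
    n_corrected <- corr$n_corrected
  }
  rmssd <- compute_rmssd(series)
  hf_power <- hf_peak <- NA_real_
  if (spectrum) {
    sp <- compute_ar_spectrum(series, resample_hz = resample_hz, order = order)
    hf_power <- sp$hf_power
    hf_peak <- sp$hf_peak
  }
  list(rmssd = rmssd,
       ln_rmssd = if (rmssd > 0) log(rmssd) else NA_real_,
       hf_power = hf_power, hf_peak = hf_peak,
       n_corrected = n_corrected)
}

#' Skew-gated natural-log transform
#'
#' Applies the natural logarithm to a vector of per-subject scalars if and
#' only if a Shapiro-Wilk test rejects normality at `alpha` and the sample
#' skewness is positive — the usual gate for positively skewed HRV metrics.
#'
#' @param values Numeric vector (one value per subject).
#' @param alpha Significance level of the normality test.
#' @param force Force the transform regardless of the gate.
#' @return A list with `values` (possibly transformed), `applied` (logical),
#'   `shapiro_p`, and `skewness`.
#' @export
ln_skew_transform <- function(values, alpha = 0.05, force = FALSE) {
  values <- as.numeric(values)
  if (length(values) < 3) stop("need at least 3 values for the normality gate")
  p <- stats::shapiro.test(values)$p.value
  sk <- e1071::skewness(values)
  apply_ln <- force || (p < alpha && sk > 0)
  if (apply_ln) {
    if (any(values <= 0)) {
      stop("nonpositive values cannot be log transformed; check upstream metrics")
    }
    values <- log(values)
  }
  list(values = values, applied = apply_ln, shapiro_p = p, skewness = sk)
}
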