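#!/usr/bin/env Rscript
# Correlational and mediational inference: zero-order Pearson correlations
# and partial correlations (adjusting for sex, age, BMI, and the HF-peak
# respiration proxy matched to each HRV metric) between the HRV metrics
# and the interference metrics, then the four single-mediator models with
# the 10,000-draw Monte Carlo indirect-effect test.

library(vagalflex)

prof <- read.csv("results/profiles.csv")
n <- nrow(prof)

cat("key HRV inter-correlations:\n")
print(pearson_fisher(prof$resting_ln_rmssd, prof$reactivity_sd))
print(pearson_fisher(prof$resting_ln_rmssd, prof$reactivity_mean))

hrv_vars <- c(ln_reactivity_sd = "hf_peak_reactivity_sd",
              reactivity_mean = "hf_peak_reactivity_mean",
              resting_ln_rmssd = "resting_hf_peak")
perf_vars <- c("interference_mean", "interference_sd")

rows <- list()
for (hv in names(hrv_vars)) {
  for (pv in perf_vars) {
    r0 <- pearson_fisher(prof[[hv]], prof[[pv]])
    covs <- prof[, c("sex", "age", "bmi", hrv_vars[[hv]])]
    pc <- partial_corr(prof[[hv]], prof[[pv]], covs)
    rows[[length(rows) + 1]] <- data.frame(
      hrv_metric = hv, performance_metric = pv,
      r = r0$r, r_p = r0$p, r_lo = r0$ci_low, r_hi = r0$ci_high,
      pcc = pc$r, pcc_p = pc$p, pcc_lo = pc$ci_low, pcc_hi = pc$ci_high)
  }
}
cors <- do.call(rbind, rows)
cat("\ncorrelations and partial correlations with interference metrics:\n")
print(cors, digits = 3)
write.csv(cors, "results/correlations.csv", row.names = FALSE)

# four mediation models: {Reactivity_SD, Reactivity_MEAN} mediating
# resting lnRMSSD -> {Interference_SD, Interference_MEAN}
models <- expand.grid(mediator = c("ln_reactivity_sd", "reactivity_mean"),
                      outcome = c("interference_sd", "interference_mean"),
                      stringsAsFactors = FALSE)
covariates <- c("age", "bmi", "sex", "resting_hf_peak")
med_list <- list()
for (i in seq_len(nrow(models))) {
  med <- mediate(prof, "resting_ln_rmssd", models$mediator[i],
                 models$outcome[i], covariates = covariates,
                 n_sims = 10000, seed = 20260920 + i)
  cat("\n")
  print(med)
  med_list[[paste(models$mediator[i], models$outcome[i], sep = "->")]] <-
    med[c("a", "se_a", "p_a", "b", "se_b", "p_b", "c", "se_c", "p_c",
          "c_prime", "se_c_prime", "p_c_prime", "indirect_point",
          "mc_ci_low", "mc_ci_high", "mc_p", "n_sims", "seed", "n",
          "classification")]
}
jsonlite::write_json(med_list, "results/mediation.json", auto_unbox = TRUE,
                     digits = NA)
cat("\nwrote results/correlations.csv and results/mediation.json\n")
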