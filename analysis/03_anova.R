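#!/usr/bin/env Rscript
# Mixed-design ANOVAs: (i) Stroop RT by congruency x emotion x social x
# vagal-flexibility tertile (linear trend coding, matching the single-df
# flexibility tests), with simple congruency x emotion interactions per
# flexibility group; (ii) lnRMSSD by period (baseline/task) x emotion x
# social x flexibility.

library(vagalflex)

prof <- read.csv("results/profiles.csv")
sessions <- read_cohort("results/cohort")
sessions <- Filter(function(s) s$subject %in% prof$subject, sessions)
flex <- setNames(prof$flexibility_tertile, prof$subject)

# long RT table: subject x condition x congruency cell means
trials <- do.call(rbind, lapply(sessions, `[[`, "trials"))
trials <- trials[!is.na(trials$rt_ms), ]
rt_long <- aggregate(rt_ms ~ subject + condition + congruency, trials, mean)
rt_long$emotion <- ifelse(rt_long$condition %in% c("HELS", "HEHS"), "high", "low")
rt_long$social <- ifelse(rt_long$condition %in% c("LEHS", "HEHS"), "high", "low")
rt_long$flex <- factor(flex[rt_long$subject], levels = c("low", "medium", "high"))

tab_rt <- mixed_anova(rt_long, "rt_ms", "subject",
                      within = c("congruency", "emotion", "social"),
                      between = "flex", flex_coding = "linear")
cat("Stroop RT mixed ANOVA (flexibility as linear trend):\n")
print(as.data.frame(tab_rt), digits = 4)

cat("\nsimple congruency x emotion interactions by flexibility group:\n")
for (g in c("low", "medium", "high")) {
  si <- simple_interaction(rt_long, "rt_ms", "subject",
                           within = c("congruency", "emotion", "social"),
                           pair = c("congruency", "emotion"),
                           between = "flex", group = g, flex_coding = "linear")
  cat(sprintf("  %-6s F(%d, %d) = %.2f, p = %.3f\n",
              g, si$df_num, si$df_den, si$F, si$p))
}

cat("\nper-condition congruency contrasts (paired t, congruent - incongruent):\n")
for (cond in vf_conditions()) {
  ct <- paired_contrast(rt_long[rt_long$condition == cond, ], "rt_ms",
                        "subject", "congruency", "congruent", "incongruent")
  cat(sprintf("  %s t(%d) = %.2f, p = %.4g\n", cond, ct$df, ct$t, ct$p))
}

# lnRMSSD ANOVA: period x emotion x social x flexibility
rows <- list()
for (s in sessions) {
  for (cond in vf_conditions()) {
    for (period in c("baseline", "task")) {
      seg <- s$segments[[paste0(cond, "_", period)]]
      rmssd <- compute_rmssd(correct_artifacts(seg)$series)
      rows[[length(rows) + 1]] <- data.frame(
        subject = s$subject, condition = cond, period = period,
        ln_rmssd = log(max(rmssd, 0.01)))
    }
  }
}
hrv_long <- do.call(rbind, rows)
hrv_long$emotion <- ifelse(hrv_long$condition %in% c("HELS", "HEHS"), "high", "low")
hrv_long$social <- ifelse(hrv_long$condition %in% c("LEHS", "HEHS"), "high", "low")
hrv_long$flex <- factor(flex[hrv_long$subject], levels = c("low", "medium", "high"))

tab_hrv <- mixed_anova(hrv_long, "ln_rmssd", "subject",
                       within = c("period", "emotion", "social"),
                       between = "flex", flex_coding = "linear")
cat("\nlnRMSSD mixed ANOVA:\n")
print(as.data.frame(tab_hrv), digits = 4)

write.csv(as.data.frame(tab_rt), "results/anova_rt.csv", row.names = FALSE)
write.csv(as.data.frame(tab_hrv), "results/anova_lnrmssd.csv", row.names = FALSE)
cat("\nwrote results/anova_rt.csv and results/anova_lnrmssd.csv\n")
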