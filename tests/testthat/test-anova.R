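test_that("mixed ANOVA matches the aov error-stratum oracle on balanced designs", {
  d <- toy_mixed_design(12, effects = list(A = 1, g = 0.5, AB = 0.7), seed = 42)
  tab <- mixed_anova(d, "y", "subject", c("A", "B"), "g",
                     flex_coding = "categorical")
  oracle <- summary(aov(y ~ g * A * B + Error(subject / (A * B)), data = d))
  pull <- function(stratum, row) {
    s <- oracle[[stratum]][[1]]
    c(ss = s[row, "Sum Sq"], df = s[row, "Df"],
      err = s["Residuals", "Sum Sq"])
  }
  g <- pull("Error: subject", "g")
  expect_equal(tab$ss_num[tab$effect == "g"], g[["ss"]], tolerance = 1e-6)
  expect_equal(tab$ss_den[tab$effect == "g"], g[["err"]], tolerance = 1e-6)
  A <- pull("Error: subject:A", "A")
  expect_equal(tab$ss_num[tab$effect == "A"], A[["ss"]], tolerance = 1e-6)
  gA <- pull("Error: subject:A", "g:A")
  expect_equal(tab$ss_num[tab$effect == "g:A"], gA[["ss"]], tolerance = 1e-6)
  AB <- pull("Error: subject:A:B", "A:B")
  expect_equal(tab$ss_num[tab$effect == "A:B"], AB[["ss"]], tolerance = 1e-6)
  expect_equal(tab$ss_den[tab$effect == "A:B"], AB[["err"]], tolerance = 1e-6)

  # eta-squared denominators: ges in [0,1]; total SS decomposes on balanced data
  expect_true(all(tab$ges >= 0 & tab$ges <= 1))
  cellmeans <- aggregate(y ~ subject + A + B, d, mean)
  total_ss <- sum((cellmeans$y - mean(cellmeans$y))^2)
  grand_ss <- sum(tab$ss_num) + attr(tab, "error_ss_total")
  expect_equal(grand_ss, total_ss, tolerance = 1e-6)
})

test_that("mixed ANOVA handles multi-level within factors against aov", {
  set.seed(7)
  N <- 12
  subj <- sprintf("s%02d", seq_len(N))
  d <- expand.grid(subject = subj, W = c("w1", "w2", "w3"),
                   stringsAsFactors = FALSE)
  d$g <- rep(c("g1", "g2"), each = N / 2)[match(d$subject, subj)]
  d$y <- rnorm(nrow(d)) + 0.4 * as.numeric(factor(d$W))
  tab <- mixed_anova(d, "y", "subject", "W", "g", flex_coding = "categorical")
  oracle <- summary(aov(y ~ g * W + Error(subject / W), data = d))
  w <- oracle[["Error: subject:W"]][[1]]
  expect_equal(tab$ss_num[tab$effect == "W"], w["W", "Sum Sq"], tolerance = 1e-6)
  expect_equal(tab$df_num[tab$effect == "W"], 2)
  expect_equal(tab$df_den[tab$effect == "W"], 20)
  expect_equal(tab$ss_den[tab$effect == "W"], w["Residuals", "Sum Sq"],
               tolerance = 1e-6)
})

test_that("linear between coding yields single-df trend tests", {
  set.seed(11)
  N <- 15
  subj <- sprintf("s%02d", seq_len(N))
  d <- expand.grid(subject = subj, A = c("a1", "a2"), stringsAsFactors = FALSE)
  flex <- rep(c("low", "medium", "high"), each = N / 3)
  d$flex <- factor(flex[match(d$subject, subj)],
                   levels = c("low", "medium", "high"))
  d$y <- rnorm(nrow(d)) + 0.8 * as.numeric(d$flex)
  tab <- mixed_anova(d, "y", "subject", "A", "flex", flex_coding = "linear")
  expect_equal(tab$df_num[tab$effect == "flex"], 1)
  expect_equal(tab$df_den[tab$effect == "flex"], N - 2)
  expect_equal(tab$df_den[tab$effect == "A"], N - 2)
  # oracle: between stratum is a regression of subject means on the score
  sm <- aggregate(y ~ subject + flex, d, mean)
  fit <- lm(y ~ as.numeric(flex), data = sm)
  ss_flex <- sum((fitted(fit) - mean(sm$y))^2) * 2  # 2 cells per subject
  expect_equal(tab$ss_num[tab$effect == "flex"], ss_flex, tolerance = 1e-6)
  expect_equal(tab$ss_den[tab$effect == "flex"], sum(resid(fit)^2) * 2,
               tolerance = 1e-6)
})

test_that("effect statistics recompute from printed sums of squares", {
  # direct arithmetic check of F and generalized eta squared assembly
  st <- anova_effect_stats(ss_num = 120, df_num = 1, ss_den = 450, df_den = 45,
                           total_error_ss = 2000)
  expect_equal(st$F, (120 / 1) / (450 / 45))
  expect_equal(st$ges, 120 / 2120)
  expect_equal(st$p, pf(st$F, 1, 45, lower.tail = FALSE))
})

test_that("ANOVA rejects unbalanced or degenerate input", {
  d <- toy_mixed_design(8, seed = 1)
  expect_error(mixed_anova(d[-1, ], "y", "subject", c("A", "B"), "g"),
               "unbalanced")
  d2 <- toy_mixed_design(8, seed = 2)
  d2$g[d2$subject == "s01"] <- "g3"
  expect_error(mixed_anova(d2, "y", "subject", c("A", "B"), "g",
                           flex_coding = "categorical"), "singleton")
})

test_that("paired contrasts and simple interactions behave on generated data", {
  set.seed(21)
  spec <- cohort_spec(interference_ms = 120, emotion_distraction_ms = 0)
  rows <- list()
  for (i in 1:40) {
    for (cond in c("LELS", "HELS")) {
      tr <- generate_trials(cond, 0.5, spec)
      agg <- aggregate(rt_ms ~ congruency, tr, mean)
      rows[[length(rows) + 1]] <- data.frame(subject = sprintf("s%02d", i),
                                             condition = cond, agg)
    }
  }
  long <- do.call(rbind, rows)
  ct <- paired_contrast(long, "rt_ms", "subject", "congruency",
                        "congruent", "incongruent")
  expect_lt(ct$t, -2)   # incongruent slower => congruent - incongruent < 0
  expect_lt(ct$p, 0.001)
  expect_error(paired_contrast(long[long$subject == "s01", ], "rt_ms",
                               "subject", "congruency", "congruent",
                               "incongruent"), "2 subjects")

  # null congruency x condition interaction: simple interaction F is tame
  long$flex <- ifelse(as.integer(substring(long$subject, 2)) <= 20, "low", "high")
  si <- simple_interaction(long, "rt_ms", "subject",
                           within = c("congruency", "condition"),
                           pair = c("congruency", "condition"),
                           between = "flex", group = "low",
                           flex_coding = "categorical")
  expect_equal(si$df_num, 1)
  expect_equal(si$df_den, 38)
  expect_gt(si$p, 0.001)
  expect_error(simple_interaction(long, "rt_ms", "subject",
                                  within = c("congruency", "condition"),
                                  pair = c("congruency", "condition"),
                                  between = "flex", group = "absent"),
               "sliced group")
})

test_that("paired-t type I error is controlled on zero-effect data", {
  set.seed(31)
  n_sim <- 300
  hits <- vapply(seq_len(n_sim), function(i) {
    d <- data.frame(subject = rep(sprintf("s%02d", 1:15), 2),
                    cond = rep(c("c1", "c2"), each = 15),
                    y = rnorm(30))
    abs(paired_contrast(d, "y", "subject", "cond", "c1", "c2")$t) < 2
  }, logical(1))
  expect_gte(mean(hits), 0.93)
})
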