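test_that("RT interference is the incongruent-congruent mean difference", {
  expect_equal(rt_interference(two_cell_trials(946.51, 1080.38)), 133.87)
  expect_equal(rt_interference(two_cell_trials(990.12, 1137.39)), 147.27)
  expect_equal(rt_interference(two_cell_trials(800, 800)), 0)
  # censored RTs are excluded from the means
  tr <- data.frame(condition = "LELS", trial_index = 1:4,
                   congruency = c("congruent", "congruent", "incongruent", "incongruent"),
                   rt_ms = c(700, NA, 900, NA), correct = c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(rt_interference(tr), 200)
  expect_error(rt_interference(tr[tr$congruency == "congruent", ]), "cell")
})

test_that("accuracy interference is a bounded proportion difference", {
  tr <- data.frame(congruency = rep(c("congruent", "incongruent"), each = 100),
                   correct = c(rep(TRUE, 100), rep(TRUE, 96), rep(FALSE, 4)))
  expect_equal(accuracy_interference(tr), -0.04)
  tr2 <- data.frame(congruency = c("congruent", "incongruent"),
                    correct = c(TRUE, FALSE))
  expect_equal(accuracy_interference(tr2), -1)
  tr3 <- data.frame(congruency = c("congruent", "incongruent"),
                    correct = c(TRUE, TRUE))
  expect_equal(accuracy_interference(tr3), 0)
})

test_that("reactivity scores follow the task-minus-baseline convention", {
  expect_equal(reactivity_score(48.72, 50.37), -1.65)
  expect_equal(reactivity_score(50, 50), 0)
  expect_equal(reactivity_score(0.266, 0.217), 0.049)  # HF-peak, same contract
  expect_error(reactivity_score(NA, 50), "missing")
})

test_that("IIV summary gives the four-condition mean and sample SD", {
  scores <- c(1.66, 1.95, 3.39, -2.14)
  s <- iiv_summary(scores)
  expect_equal(s$mean, 1.215)
  expect_equal(s$sd, sd(scores))
  expect_equal(round(s$sd, 3), 2.361)  # hand-evaluated n-1 formula
  expect_equal(iiv_summary(rep(5, 4))$sd, 0)
  expect_error(iiv_summary(c(1, 2, 3)), "exactly 4")
  # shift invariance / scale equivariance of the SD
  expect_equal(iiv_summary(scores + 100)$sd, s$sd)
  expect_equal(iiv_summary(3 * scores)$sd, 3 * s$sd)
  # population-SD option
  expect_equal(iiv_summary(scores, denominator = "n")$sd,
               sqrt(mean((scores - mean(scores))^2)))
})

test_that("outlier exclusion is single-pass with a strict 3 SD rule", {
  set.seed(5)
  base <- rnorm(40)
  prof <- data.frame(subject = sprintf("s%02d", 1:41),
                     v1 = c(base, mean(base) + 5 * sd(base)),
                     v2 = rnorm(41))
  res <- exclude_outliers(prof, c("v1", "v2"))
  expect_equal(nrow(res$profiles), 40)
  expect_equal(res$exclusions$subject, "s41")
  expect_equal(res$exclusions$variable, "v1")

  # the rule is strict: z just under 3 retained, just over 3 excluded
  set.seed(6)
  base2 <- rnorm(60)
  z_of <- function(v) {
    x <- c(base2, v)
    abs(v - mean(x)) / sd(x)
  }
  v_in <- uniroot(function(v) z_of(v) - 2.99, c(0, 50))$root
  v_out <- uniroot(function(v) z_of(v) - 3.01, c(0, 50))$root
  keep <- data.frame(subject = as.character(1:61), v = c(base2, v_in))
  drop <- data.frame(subject = as.character(1:61), v = c(base2, v_out))
  expect_equal(nrow(exclude_outliers(keep, "v")$profiles), 61)
  expect_equal(nrow(exclude_outliers(drop, "v")$profiles), 60)

  expect_error(exclude_outliers(prof, "nope"), "absent")
})

test_that("tertile split is rank-based with near-equal groups", {
  g9 <- tertile_split(1:9)
  expect_equal(as.vector(table(g9)), c(3, 3, 3))
  expect_equal(as.character(g9[1:3]), rep("low", 3))

  set.seed(9)
  g47 <- tertile_split(rnorm(47))
  expect_equal(as.vector(table(g47)), c(16, 15, 16))
  expect_true(max(table(tertile_split(rnorm(46)))) -
                min(table(tertile_split(rnorm(46)))) <= 1)
  expect_error(tertile_split(c(1, 2)), "at least 3")
  expect_error(tertile_split(rep(1, 10)), "distinct")
  # ties broken by stable order
  gt <- tertile_split(c(5, 5, 5, 1, 9))
  expect_equal(as.character(gt), c("low", "medium", "high", "low", "high"))
})

test_that("cohort-level reactivity means decompose linearly", {
  coh <- small_cohort()
  prof <- build_profiles(coh, spectra = "none")
  task_means <- base_means <- numeric(length(coh$sessions))
  for (i in seq_along(coh$sessions)) {
    ses <- coh$sessions[[i]]
    tk <- bl <- numeric(4)
    for (j in seq_along(vf_conditions())) {
      cond <- vf_conditions()[j]
      tk[j] <- compute_rmssd(correct_artifacts(ses$segments[[paste0(cond, "_task")]])$series)
      bl[j] <- compute_rmssd(correct_artifacts(ses$segments[[paste0(cond, "_baseline")]])$series)
    }
    task_means[i] <- mean(tk); base_means[i] <- mean(bl)
  }
  expect_equal(mean(prof$reactivity_mean), mean(task_means) - mean(base_means))
})

test_that("interference recovery from generated trials is within sampling error", {
  spec <- cohort_spec(interference_ms = 120, emotion_distraction_ms = 0)
  est <- vapply(1:30, function(i) {
    rt_interference(generate_trials("LELS", 0.5, spec, seed = i))
  }, numeric(1))
  se <- sqrt(2 * (spec$rt_sigma_ms^2 + spec$rt_tau_ms^2) / 32)
  expect_lt(abs(mean(est) - 120), 2 * se / sqrt(30))
})
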