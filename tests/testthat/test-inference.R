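test_that("Fisher-z confidence intervals reproduce hand-checked bounds", {
  ci654 <- fisher_ci(0.654, 47)
  expect_equal(round(ci654[1], 3), 0.452)
  # upper bound: the exact formula gives 0.79236 (cor.test agrees); a
  # commonly quoted value of 0.793 reflects rounding of r upstream
  expect_equal(ci654[2], 0.793, tolerance = 0.0011)
  expect_equal(round(fisher_ci(0.463, 47), 3), c(0.203, 0.662))
  expect_equal(round(fisher_ci(-0.374, 47), 3), c(-0.597, -0.097))
  expect_equal(round(fisher_ci(-0.378, 47, k = 4), 3), c(-0.609, -0.088))
  expect_error(fisher_ci(1, 30), "degenerate")
  expect_error(fisher_ci(0.5, 5, k = 3), "too small")
})

test_that("Fisher CI contains the estimate and narrows with n", {
  set.seed(3)
  for (i in 1:20) {
    r <- runif(1, -0.95, 0.95)
    n <- sample(10:200, 1)
    ci <- fisher_ci(r, n)
    expect_true(ci[1] <= r && r <= ci[2])
    ci_big <- fisher_ci(r, n + 50)
    expect_lt(diff(ci_big), diff(ci))
  }
})

test_that("pearson_fisher CI covers a true null about 95% of the time", {
  set.seed(42)
  n_sim <- 1000
  misses <- vapply(seq_len(n_sim), function(i) {
    x <- rnorm(30); y <- rnorm(30)
    res <- pearson_fisher(x, y)
    res$ci_low > 0 || res$ci_high < 0
  }, logical(1))
  expect_lt(abs(mean(misses) - 0.05), 0.02)
  expect_error(pearson_fisher(rep(1, 10), rnorm(10)), "variance")
})

test_that("partial correlation equals brute-force residualization and reduces to Pearson", {
  set.seed(8)
  n <- 10
  cv <- data.frame(c1 = rnorm(n), c2 = rnorm(n))
  x <- rnorm(n) + cv$c1
  y <- rnorm(n) + 0.5 * cv$c2
  pc <- partial_corr(x, y, cv)
  # oracle: correlate lm residuals directly
  rx <- resid(lm(x ~ c1 + c2, data = cv))
  ry <- resid(lm(y ~ c1 + c2, data = cv))
  expect_equal(pc$r, cor(rx, ry), tolerance = 1e-10)
  expect_equal(pc$df, n - 4)

  p0 <- partial_corr(x, y, NULL)
  pf <- pearson_fisher(x, y)
  expect_identical(p0$r, pf$r)
  expect_identical(p0$ci_low, pf$ci_low)
  expect_error(partial_corr(x, y, data.frame(a = cv$c1, b = 2 * cv$c1)), "collinear")
})

test_that("path models match the normal-equations oracle", {
  set.seed(15)
  n <- 25
  prof <- data.frame(x = rnorm(n), cov1 = rnorm(n))
  prof$m <- 0.7 * prof$x + rnorm(n)
  prof$y <- 0.5 * prof$m + 0.2 * prof$x + rnorm(n)
  fits <- fit_path_models(prof, "x", "m", "y", "cov1")

  ols <- function(X, y) {
    XtXi <- solve(t(X) %*% X)
    beta <- XtXi %*% t(X) %*% y
    res <- y - X %*% beta
    s2 <- sum(res^2) / (n - ncol(X))
    list(beta = drop(beta), se = sqrt(diag(XtXi) * s2))
  }
  X2 <- cbind(1, prof$x, prof$cov1)
  o2 <- ols(X2, prof$m)
  expect_equal(fits$paths$a, o2$beta[2], tolerance = 1e-8)
  expect_equal(fits$paths$se_a, o2$se[2], tolerance = 1e-8)
  X3 <- cbind(1, prof$x, prof$m, prof$cov1)
  o3 <- ols(X3, prof$y)
  expect_equal(fits$paths$b, o3$beta[3], tolerance = 1e-8)
  expect_equal(fits$paths$se_b, o3$se[3], tolerance = 1e-8)
  expect_equal(fits$paths$c_prime, o3$beta[2], tolerance = 1e-8)

  # exact relation, no covariates, SE 0
  prof2 <- data.frame(x = 1:10, m = rnorm(10), y = 2 * (1:10))
  f2 <- suppressWarnings(fit_path_models(prof2, "x", "m", "y"))  # exact fit
  expect_equal(f2$paths$c, 2)
  expect_lt(f2$paths$se_c, 1e-10)
})

test_that("path-a estimates control type I error under a null mediator", {
  set.seed(33)
  n_sim <- 1000
  z <- vapply(seq_len(n_sim), function(i) {
    prof <- data.frame(x = rnorm(40), m = rnorm(40), y = rnorm(40))
    f <- fit_path_models(prof, "x", "m", "y")
    abs(f$paths$a / f$paths$se_a)
  }, numeric(1))
  expect_gte(mean(z < 1.96), 0.93)
})

test_that("Monte Carlo indirect test handles point masses and respects the seed", {
  r1 <- mc_indirect(0.5, 0, 0.4, 0, n_sims = 1000, seed = 1)
  expect_equal(c(r1$ci_low, r1$ci_high), c(0.2, 0.2))
  expect_equal(r1$p, 0)
  r2 <- mc_indirect(0, 0, 0.7, 0.1, n_sims = 1000, seed = 1)
  expect_equal(c(r2$ci_low, r2$ci_high), c(0, 0))
  expect_equal(r2$p, 1)
  expect_error(mc_indirect(0.5, -0.1, 0.4, 0.1), "nonnegative")

  a <- mc_indirect(0.6, 0.15, 0.4, 0.15, seed = 77)
  b <- mc_indirect(0.6, 0.15, 0.4, 0.15, seed = 77)
  expect_identical(a$ci_low, b$ci_low)
  expect_true(a$ci_low <= a$point && a$point <= a$ci_high)
})

test_that("Monte Carlo CI width is nondecreasing in each standard error", {
  base <- mc_indirect(0.6, 0.10, 0.4, 0.10, n_sims = 1e6, seed = 5)
  wa <- mc_indirect(0.6, 0.20, 0.4, 0.10, n_sims = 1e6, seed = 5)
  wb <- mc_indirect(0.6, 0.10, 0.4, 0.20, n_sims = 1e6, seed = 5)
  expect_gt(wa$ci_high - wa$ci_low, base$ci_high - base$ci_low)
  expect_gt(wb$ci_high - wb$ci_low, base$ci_high - base$ci_low)
})

test_that("mediate classifies a pure-noise mediator as no mediation", {
  set.seed(55)
  prof <- data.frame(x = rnorm(60))
  prof$y <- 0.8 * prof$x + rnorm(60, 0, 0.5)
  prof$m <- rnorm(60)
  res <- mediate(prof, "x", "m", "y", seed = 2)
  expect_equal(res$classification, "none")
  expect_true(res$mc_ci_low <= 0 && res$mc_ci_high >= 0)
})

test_that("null-mediator indirect CIs cover zero at the nominal rate", {
  set.seed(66)
  n_sim <- 400
  sig <- vapply(seq_len(n_sim), function(i) {
    prof <- data.frame(x = rnorm(50), m = rnorm(50))
    prof$y <- rnorm(50)
    mc <- with(fit_path_models(prof, "x", "m", "y")$paths,
               mc_indirect(a, se_a, b, se_b, n_sims = 2000))
    mc$ci_low > 0 || mc$ci_high < 0
  }, logical(1))
  expect_lte(mean(sig), 0.07)
})
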