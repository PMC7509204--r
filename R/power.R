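#' Monte Carlo power of the indirect-effect test
#'
#' Simulates replicate datasets from the standardized single-mediator
#' model `M = a*X + e_m`, `Y = b*M + c'*X + e_y` (X standard normal;
#' residual variances chosen so M and Y have unit variance), fits the two
#' path regressions per replicate, and applies the chosen indirect-effect
#' test at level `alpha`. Power is the rejection proportion.
#'
#' Three tests are available. `"mc_ci"` (the default) is the Monte Carlo
#' percentile CI on `a*b` from the fitted path regressions — the same
#' inferential test the analysis pipeline uses ([mc_indirect()]).
#' `"joint_significance"` requires both regression paths (a from `M ~ X`,
#' b from `Y ~ M + X`) to be individually significant.
#' `"joint_correlation"` requires the two bivariate *correlations* (X-M
#' and M-Y) to be individually significant; this is the construct behind
#' the common analytic sample-size calculators that take "path a and b
#' correlations" as input, and with `c_prime = 0` the M-Y correlation
#' equals path b. The correlation test is noticeably more liberal than
#' the regression-based tests (it ignores the uncertainty added by the
#' partialled predictor), so required sample sizes differ by several
#' subjects between the options.
#'
#' All regressions are computed in closed form across replicates, so large
#' replicate counts are practical; results are reproducible given `seed`.
#'
#' @param n Sample size per replicate (>= 10).
#' @param a,b,c_prime Standardized path coefficients (|path| < 1).
#' @param alpha Two-sided error rate.
#' @param n_reps Number of simulated replicates.
#' @param n_sims Monte Carlo draws per replicate for the `mc_ci` test.
#' @param test `"mc_ci"`, `"joint_significance"`, or `"joint_correlation"`.
#' @param seed Optional integer seed.
#' @return List with `n`, `power`, `mc_se` (binomial standard error of the
#'   power estimate), `test`, `n_reps`.
#' @export
simulate_power <- function(n, a = 0.4, b = 0.4, c_prime = 0, alpha = 0.05,
                           n_reps = 10000, n_sims = 10000,
                           test = c("mc_ci", "joint_significance",
                                    "joint_correlation"),
                           seed = NULL) {
  test <- match.arg(test)
  if (n < 10) stop("n must be >= 10")
  if (abs(a) >= 1 || abs(b) >= 1 || abs(c_prime) >= 1) stop("|paths| must be < 1")
  s2_m <- 1 - a^2
  s2_y <- 1 - b^2 - c_prime^2 - 2 * a * b * c_prime
  if (s2_m <= 0 || s2_y <= 0) stop("implied covariance matrix not positive definite")
  if (!is.null(seed)) set.seed(seed)

  X <- matrix(stats::rnorm(n * n_reps), n, n_reps)
  M <- a * X + sqrt(s2_m) * matrix(stats::rnorm(n * n_reps), n, n_reps)
  Y <- b * M + c_prime * X + sqrt(s2_y) * matrix(stats::rnorm(n * n_reps), n, n_reps)
  X <- sweep(X, 2, colMeans(X)); M <- sweep(M, 2, colMeans(M))
  Y <- sweep(Y, 2, colMeans(Y))
  Sxx <- colSums(X^2); Smm <- colSums(M^2); Syy <- colSums(Y^2)
  Sxm <- colSums(X * M); Sxy <- colSums(X * Y); Smy <- colSums(M * Y)

  a_hat <- Sxm / Sxx
  rss_a <- Smm - a_hat * Sxm
  se_a <- sqrt(rss_a / (n - 2) / Sxx)

  det <- Smm * Sxx - Sxm^2
  b_hat <- (Sxx * Smy - Sxm * Sxy) / det
  cp_hat <- (Smm * Sxy - Sxm * Smy) / det
  rss_y <- Syy - b_hat * Smy - cp_hat * Sxy
  se_b <- sqrt(pmax(rss_y, 0) / (n - 3) * Sxx / det)

  reject <- if (test == "joint_significance") {
    abs(a_hat / se_a) > stats::qt(1 - alpha / 2, n - 2) &
      abs(b_hat / se_b) > stats::qt(1 - alpha / 2, n - 3)
  } else if (test == "joint_correlation") {
    r_xm <- Sxm / sqrt(Sxx * Smm)
    r_my <- Smy / sqrt(Smm * Syy)
    t_of_r <- function(r) abs(r) * sqrt((n - 2) / (1 - r^2))
    crit <- stats::qt(1 - alpha / 2, n - 2)
    t_of_r(r_xm) > crit & t_of_r(r_my) > crit
  } else {
    # percentile CI on a*b excludes 0 iff the proportion of negative (or
    # positive) product draws falls below alpha/2
    out <- logical(n_reps)
    chunk <- max(1L, floor(2e7 / n_sims))
    for (start in seq(1L, n_reps, by = chunk)) {
      idx <- start:min(start + chunk - 1L, n_reps)
      za <- matrix(stats::rnorm(length(idx) * n_sims), length(idx), n_sims)
      zb <- matrix(stats::rnorm(length(idx) * n_sims), length(idx), n_sims)
      prod_neg <- rowMeans((a_hat[idx] + se_a[idx] * za) *
                             (b_hat[idx] + se_b[idx] * zb) <= 0)
      out[idx] <- prod_neg < alpha / 2 | prod_neg > 1 - alpha / 2
    }
    out
  }
  power <- mean(reject)
  list(n = n, power = power, mc_se = sqrt(power * (1 - power) / n_reps),
       test = test, n_reps = n_reps)
}

#' Required sample size for the indirect effect
#'
#' Smallest `n` in `n_range` achieving `target_power` for the
#' indirect-effect test, found by bisection over [simulate_power()]. The
#' per-candidate seed is derived deterministically from `seed` and the
#' candidate `n`, so each candidate's power estimate does not depend on
#' the bisection path.
#'
#' @inheritParams simulate_power
#' @param target_power Power to achieve (0, 1).
#' @param n_range Integer vector `c(min, max)` to search.
#' @return List with `n` (the estimate), `power_at_n`, `curve` (data frame
#'   of every candidate evaluated), `target_power`, `test`.
#' @export
required_n <- function(a = 0.4, b = 0.4, c_prime = 0, alpha = 0.05,
                       target_power = 0.8, n_range = c(20, 200),
                       n_reps = 10000, n_sims = 10000,
                       test = c("mc_ci", "joint_significance",
                                "joint_correlation"), seed = 1L) {
  test <- match.arg(test)
  if (length(n_range) != 2 || n_range[1] >= n_range[2]) {
    stop("n_range must be c(min, max) with min < max")
  }
  if (target_power <= 0 || target_power >= 1) stop("target_power must be in (0, 1)")
  cache <- new.env(parent = emptyenv())
  eval_n <- function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    res <- simulate_power(n, a = a, b = b, c_prime = c_prime, alpha = alpha,
                          n_reps = n_reps, n_sims = n_sims, test = test,
                          seed = as.integer((as.numeric(seed) * 131 + n) %%
                                              2147483647))
    cache[[key]] <- res$power
    res$power
  }
  lo <- as.integer(n_range[1]); hi <- as.integer(n_range[2])
  p_hi <- eval_n(hi)
  if (p_hi < target_power) {
    stop(sprintf("target power %.2f unreachable within n_range (power %.3f at n = %d)",
                 target_power, p_hi, hi))
  }
  p_lo <- eval_n(lo)
  if (p_lo >= target_power) {
    hi <- lo
  } else {
    while (hi - lo > 1) {
      mid <- as.integer(floor((lo + hi) / 2))
      if (eval_n(mid) >= target_power) hi <- mid else lo <- mid
    }
  }
  ns <- sort(as.integer(ls(cache)))
  curve <- data.frame(n = ns,
                      power = vapply(as.character(ns), function(k) cache[[k]],
                                     numeric(1)))
  list(n = hi, power_at_n = cache[[as.character(hi)]], curve = curve,
       target_power = target_power, test = test, n_reps = n_reps)
}
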