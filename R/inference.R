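#' Fisher-z confidence interval for a (partial) correlation
#'
#' `tanh(atanh(r) +/- z * / sqrt(n - 3 - k))`, where `k` is the number of
#' partialled covariates (0 for a zero-order correlation).
#'
#' @param r Correlation estimate, strictly inside (-1, 1).
#' @param n Sample size.
#' @param k Number of partialled covariates.
#' @param alpha Two-sided error rate.
#' @return Numeric vector `c(lower, upper)` on the correlation scale.
#' @export
fisher_ci <- function(r, n, k = 0, alpha = 0.05) {
  if (abs(r) >= 1) stop("|r| = 1: Fisher interval is degenerate")
  if (n - 3 - k <= 0) stop("n too small for a Fisher interval with k covariates")
  z <- atanh(r)
  se <- 1 / sqrt(n - 3 - k)
  q <- stats::qnorm(1 - alpha / 2)
  tanh(c(z - q * se, z + q * se))
}

correlation_result <- function(r, n, k, p, ci, alpha) {
  structure(list(r = r, n = n, k = k, df = n - 2 - k, p = p,
                 ci_low = ci[1], ci_high = ci[2], alpha = alpha),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s = %.3f, n = %d, df = %d, p = %.4g, %d%% CI [%.3f, %.3f]\n",
              if (x$k > 0) "pcc" else "r", x$r, x$n, x$df, x$p,
              round(100 * (1 - x$alpha)), x$ci_low, x$ci_high))
  invisible(x)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y Numeric vectors.
#' @param alpha Two-sided error rate.
#' @return A `correlation_result`: r, n, df = n - 2, two-tailed p from the
#'   t distribution, and Fisher-z CI.
#' @export
pearson_fisher <- function(x, y, alpha = 0.05) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  r <- stats::cor(x, y)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  correlation_result(r, n, 0L, p, fisher_ci(r, n, 0, alpha), alpha)
}

#' Partial Pearson correlation with Fisher-z confidence interval
#'
#' Correlation of the residuals of `x` and `y` after regressing each on
#' the covariates; p from the t distribution with `n - 2 - k` df and CI on
#' the Fisher scale with standard error `1 / sqrt(n - 3 - k)`.
#'
#' @param x,y Numeric vectors.
#' @param covariates Data frame or matrix of covariates (k columns); with
#'   zero columns this reduces exactly to [pearson_fisher()].
#' @param alpha Two-sided error rate.
#' @return A `correlation_result`.
#' @export
partial_corr <- function(x, y, covariates = NULL, alpha = 0.05) {
  if (is.null(covariates) || NCOL(covariates) == 0) {
    return(pearson_fisher(x, y, alpha))
  }
  cv <- as.matrix(as.data.frame(covariates))
  ok <- stats::complete.cases(x, y, cv)
  x <- x[ok]; y <- y[ok]; cv <- cv[ok, , drop = FALSE]
  n <- length(x); k <- ncol(cv)
  if (n < k + 4) stop("need n >= k + 4")
  X <- cbind(1, cv)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("collinear covariates")
  rx <- stats::resid(stats::lm.fit(X, x))
  ry <- stats::resid(stats::lm.fit(X, y))
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) stop("zero residual variance")
  r <- stats::cor(rx, ry)
  df <- n - 2 - k
  tt <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = df)
  correlation_result(r, n, as.integer(k), p, fisher_ci(r, n, k, alpha), alpha)
}

#' Fit the three mediation path models
#'
#' Ordinary least squares with intercept, all models sharing the covariate
#' set: Model 1 regresses the outcome on the predictor (total effect, path
#' c); Model 2 regresses the mediator on the predictor (path a); Model 3
#' adds the mediator to Model 1 (direct effect c' and mediator effect b).
#'
#' @param profiles Data frame of per-subject variables.
#' @param x,mediator,y Column names of predictor, mediator, outcome.
#' @param covariates Character vector of covariate column names.
#' @return List with the three `lm` fits (`model1..model3`), the extracted
#'   `paths` (a, b, c, c_prime with standard errors and p values), and `n`.
#' @export
fit_path_models <- function(profiles, x, mediator, y, covariates = character()) {
  vars <- c(x, mediator, y, covariates)
  missing_vars <- setdiff(vars, names(profiles))
  if (length(missing_vars)) stop("missing columns: ", paste(missing_vars, collapse = ", "))
  dat <- profiles[stats::complete.cases(profiles[, vars, drop = FALSE]), , drop = FALSE]
  if (nrow(dat) <= length(covariates) + 3) stop("too few complete cases")
  rhs <- function(terms) paste(terms, collapse = " + ")
  m1 <- stats::lm(stats::reformulate(c(x, covariates), y), data = dat)
  m2 <- stats::lm(stats::reformulate(c(x, covariates), mediator), data = dat)
  m3 <- stats::lm(stats::reformulate(c(x, mediator, covariates), y), data = dat)
  if (any(is.na(stats::coef(m1))) || any(is.na(stats::coef(m2))) ||
      any(is.na(stats::coef(m3)))) {
    stop("rank-deficient design in path models")
  }
  pick <- function(fit, term) {
    s <- summary(fit)$coefficients
    c(est = s[term, 1], se = s[term, 2], p = s[term, 4])
  }
  c_ <- pick(m1, x); a_ <- pick(m2, x); b_ <- pick(m3, mediator); cp <- pick(m3, x)
  list(model1 = m1, model2 = m2, model3 = m3, n = nrow(dat),
       paths = list(c = c_[["est"]], se_c = c_[["se"]], p_c = c_[["p"]],
                    a = a_[["est"]], se_a = a_[["se"]], p_a = a_[["p"]],
                    b = b_[["est"]], se_b = b_[["se"]], p_b = b_[["p"]],
                    c_prime = cp[["est"]], se_c_prime = cp[["se"]],
                    p_c_prime = cp[["p"]]))
}

#' Monte Carlo test of the indirect effect a*b
#'
#' Draws `a*` and `b*` independently from normal distributions centered at
#' the estimates with the given standard errors (the two paths come from
#' different fitted models, so no covariance term is used), forms the
#' products, and returns the percentile confidence interval and a
#' two-tailed p value `2 * min(P(ab <= 0), P(ab >= 0))`.
#'
#' @param a,se_a,b,se_b Path estimates and standard errors (SEs >= 0).
#' @param n_sims Number of Monte Carlo draws.
#' @param seed Optional integer seed.
#' @param alpha Two-sided error rate for the percentile interval.
#' @return List with `point` (a*b), `ci_low`, `ci_high`, `p`, `n_sims`.
#' @export
mc_indirect <- function(a, se_a, b, se_b, n_sims = 10000, seed = NULL,
                        alpha = 0.05) {
  if (se_a < 0 || se_b < 0) stop("standard errors must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  prod_draws <- stats::rnorm(n_sims, a, se_a) * stats::rnorm(n_sims, b, se_b)
  ci <- unname(stats::quantile(prod_draws, c(alpha / 2, 1 - alpha / 2)))
  p <- min(2 * min(mean(prod_draws <= 0), mean(prod_draws >= 0)), 1)
  list(point = a * b, ci_low = ci[1], ci_high = ci[2], p = p, n_sims = n_sims)
}

#' Single-mediator analysis with Monte Carlo indirect-effect test
#'
#' Orchestrates the three path models and the Monte Carlo test, then
#' classifies the result: `"full"` mediation when the total effect c is
#' significant, the indirect effect is significant, and the direct effect
#' c' is not; `"partial"` when all three are significant; `"none"`
#' otherwise.
#'
#' @inheritParams fit_path_models
#' @param n_sims,seed,alpha Passed to [mc_indirect()].
#' @return An object of class `mediation_result` with all paths, SEs, the
#'   indirect point estimate and Monte Carlo CI/p, `n`, `seed`, and
#'   `classification`.
#' @export
mediate <- function(profiles, x, mediator, y, covariates = character(),
                    n_sims = 10000, seed = NULL, alpha = 0.05) {
  fits <- fit_path_models(profiles, x, mediator, y, covariates)
  p <- fits$paths
  mc <- mc_indirect(p$a, p$se_a, p$b, p$se_b, n_sims = n_sims, seed = seed,
                    alpha = alpha)
  indirect_sig <- mc$ci_low > 0 || mc$ci_high < 0
  classification <- if (p$p_c < alpha && indirect_sig && p$p_c_prime >= alpha) {
    "full"
  } else if (p$p_c < alpha && indirect_sig && p$p_c_prime < alpha) {
    "partial"
  } else "none"
  structure(c(p, list(indirect_point = mc$point, mc_ci_low = mc$ci_low,
                      mc_ci_high = mc$ci_high, mc_p = mc$p, n_sims = n_sims,
                      seed = seed, n = fits$n, x = x, mediator = mediator,
                      y = y, covariates = covariates, alpha = alpha,
                      classification = classification)),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation of %s -> %s -> %s (n = %d)\n", x$x, x$mediator, x$y, x$n))
  cat(sprintf("  a = %.4f (SE %.4f, p = %.4g)\n", x$a, x$se_a, x$p_a))
  cat(sprintf("  b = %.4f (SE %.4f, p = %.4g)\n", x$b, x$se_b, x$p_b))
  cat(sprintf("  c = %.4f (SE %.4f, p = %.4g), c' = %.4f (SE %.4f, p = %.4g)\n",
              x$c, x$se_c, x$p_c, x$c_prime, x$se_c_prime, x$p_c_prime))
  cat(sprintf("  indirect a*b = %.4f, %d%% MC CI [%.4f, %.4f], p = %.4g (%d sims)\n",
              x$indirect_point, round(100 * (1 - x$alpha)), x$mc_ci_low,
              x$mc_ci_high, x$mc_p, x$n_sims))
  cat(sprintf("  classification: %s mediation\n", x$classification))
  invisible(x)
}
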