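# Orthonormal basis for one within factor: first column is the (scaled)
# intercept, the rest span the factor's contrast space.
orthonormal_contrasts <- function(n_levels) {
  q <- qr.Q(qr(cbind(1, stats::contr.helmert(n_levels))))
  # canonical sign: make each column's first nonzero entry positive
  for (j in seq_len(ncol(q))) {
    nz <- which(abs(q[, j]) > 1e-12)[1]
    if (q[nz, j] < 0) q[, j] <- -q[, j]
  }
  q
}

rss_fit <- function(Z, X = NULL) {
  if (is.null(X)) return(sum(Z^2))
  sum(stats::lm.fit(X, Z)$residuals^2)
}

# Core decomposition shared by mixed_anova() and simple_interaction().
# Returns per-stratum contrast scores and the between design.
vf_anova_engine <- function(data, dv, subject, within, between = NULL,
                            flex_coding = c("linear", "categorical")) {
  flex_coding <- match.arg(flex_coding)
  stopifnot(is.data.frame(data), all(c(dv, subject, within, between) %in% names(data)))
  for (w in within) data[[w]] <- factor(data[[w]])
  data[[subject]] <- factor(data[[subject]])

  # aggregate to one cell mean per subject x within-cell
  agg <- stats::aggregate(data[[dv]],
                          by = c(list(data[[subject]]),
                                 lapply(within, function(w) data[[w]])),
                          FUN = mean)
  names(agg) <- c(subject, within, dv)
  lvls <- lapply(within, function(w) levels(agg[[w]]))
  m <- prod(lengths(lvls))
  cells <- do.call(expand.grid, c(stats::setNames(lvls, within),
                                  list(stringsAsFactors = FALSE)))
  subjects <- levels(agg[[subject]])
  N <- length(subjects)
  if (nrow(agg) != N * m) {
    stop("unbalanced within-subject cells: every subject needs every cell")
  }
  key_data <- do.call(paste, c(agg[within], sep = "\r"))
  key_cells <- do.call(paste, c(cells, sep = "\r"))
  Y <- matrix(NA_real_, N, m, dimnames = list(subjects, key_cells))
  Y[cbind(match(agg[[subject]], subjects), match(key_data, key_cells))] <- agg[[dv]]
  if (anyNA(Y)) stop("unbalanced within-subject cells: every subject needs every cell")

  qs <- lapply(lengths(lvls), orthonormal_contrasts)
  level_idx <- lapply(seq_along(within),
                      function(f) match(cells[[f]], lvls[[f]]))

  basis_for <- function(in_set) {
    # columns: all combinations of contrast indices for factors in the subset
    contrast_cols <- lapply(seq_along(within), function(f) {
      if (in_set[f]) seq_len(lengths(lvls)[f] - 1) + 1L else 1L
    })
    combos <- do.call(expand.grid, contrast_cols)
    B <- matrix(1, m, nrow(combos))
    for (f in seq_along(within)) {
      B <- B * qs[[f]][level_idx[[f]], combos[[f]], drop = TRUE]
    }
    B
  }

  subsets <- lapply(0:(2^length(within) - 1), function(mask) {
    as.logical(bitwAnd(mask, 2^(seq_along(within) - 1)))
  })
  strata <- lapply(subsets, function(in_set) {
    list(factors = within[in_set], Z = Y %*% basis_for(in_set))
  })

  X1 <- NULL; p_between <- 0L; group <- NULL
  if (!is.null(between)) {
    bvals <- data[[between]][match(subjects, data[[subject]])]
    group <- bvals
    if (flex_coding == "linear") {
      score <- if (is.numeric(bvals)) bvals else as.numeric(factor(bvals))
      X1 <- matrix(score - mean(score), ncol = 1,
                   dimnames = list(NULL, between))
    } else {
      g <- factor(bvals)
      if (min(table(g)) < 2) stop("singleton between-subjects group")
      X1 <- stats::model.matrix(~g, contrasts.arg = list(g = "contr.sum"))[, -1, drop = FALSE]
      colnames(X1) <- paste0(between, seq_len(ncol(X1)))
    }
    p_between <- ncol(X1)
  }
  list(strata = strata, subsets = subsets, within = within, between = between,
       X1 = X1, p_between = p_between, N = N, group = group)
}

#' Mixed-design ANOVA with generalized eta squared
#'
#' Univariate mixed-model decomposition for fully crossed within-subject
#' factors (on subject cell means) and one between-subjects term. Each
#' within effect is projected onto an orthonormal contrast basis; the
#' resulting subject scores form a stratum in which the within effect, its
#' interaction with the between term, and the effect-by-subject error are
#' estimated by (Type-III style) regression. The between term is tested
#' against subject-within-group error. Generalized eta squared for every
#' effect is `SS_effect / (SS_effect + sum of all error SS across all
#' strata)`.
#'
#' @param data Long data frame (one row per subject x cell, or raw trials,
#'   which are first averaged to cell means).
#' @param dv,subject Column names of the response and subject id.
#' @param within Character vector of within-subject factor columns.
#' @param between Optional between-subjects column (e.g. the vagal
#'   flexibility tertile).
#' @param flex_coding `"linear"` scores an ordered between group 1..G and
#'   enters it as a single-df numeric trend (the default; for a tertile
#'   split this tests the linear flexibility trend with `N - 2` error df);
#'   `"categorical"` enters it as a sum-contrast factor with G - 1 df.
#' @return Data frame of class `vf_anova` with one row per effect:
#'   `effect`, `ss_num`, `ss_den`, `df_num`, `df_den`, `F`, `p`, `ges`.
#' @export
mixed_anova <- function(data, dv, subject, within, between = NULL,
                        flex_coding = c("linear", "categorical")) {
  eng <- vf_anova_engine(data, dv, subject, within, between, flex_coding)
  X1 <- eng$X1; N <- eng$N
  ones <- matrix(1, N, 1)
  rows <- list()
  error_ss <- 0
  for (s in seq_along(eng$strata)) {
    st <- eng$strata[[s]]
    d <- ncol(st$Z)
    Xfull <- cbind(ones, X1)
    rss_full <- rss_fit(st$Z, Xfull)
    if (length(st$factors) == 0) {
      if (!is.null(X1)) {
        ss_b <- rss_fit(st$Z, ones) - rss_full
        rows[[length(rows) + 1]] <- data.frame(
          effect = eng$between, ss_num = ss_b, ss_den = rss_full,
          df_num = eng$p_between, df_den = N - 1 - eng$p_between)
      }
      error_ss <- error_ss + rss_full
    } else {
      ss_w <- rss_fit(st$Z, X1) - rss_full   # within main effect (intercept block)
      eff <- paste(st$factors, collapse = ":")
      df_err <- d * (N - 1 - eng$p_between)
      rows[[length(rows) + 1]] <- data.frame(
        effect = eff, ss_num = ss_w, ss_den = rss_full,
        df_num = d, df_den = df_err)
      if (!is.null(X1)) {
        ss_i <- rss_fit(st$Z, ones) - rss_full
        rows[[length(rows) + 1]] <- data.frame(
          effect = paste(c(eng$between, st$factors), collapse = ":"),
          ss_num = ss_i, ss_den = rss_full,
          df_num = d * eng$p_between, df_den = df_err)
      }
      error_ss <- error_ss + rss_full
    }
  }
  tab <- do.call(rbind, rows)
  tab$F <- (tab$ss_num / tab$df_num) / (tab$ss_den / tab$df_den)
  tab$p <- stats::pf(tab$F, tab$df_num, tab$df_den, lower.tail = FALSE)
  tab$ges <- tab$ss_num / (tab$ss_num + error_ss)
  class(tab) <- c("vf_anova", "data.frame")
  attr(tab, "error_ss_total") <- error_ss
  tab
}

#' Effect statistics from printed sums of squares
#'
#' Recomputes F, p, and generalized eta squared for one effect directly
#' from its numerator and denominator sums of squares and degrees of
#' freedom, with `ges = ss_num / (ss_num + total_error_ss)` where
#' `total_error_ss` sums the error SS of every stratum in the design.
#'
#' @param ss_num,df_num Effect sum of squares and df.
#' @param ss_den,df_den Error-stratum sum of squares and df.
#' @param total_error_ss Sum of all error SS across all strata.
#' @return List with `F`, `p`, `ges`.
#' @export
anova_effect_stats <- function(ss_num, df_num, ss_den, df_den, total_error_ss) {
  F <- (ss_num / df_num) / (ss_den / df_den)
  list(F = F, p = stats::pf(F, df_num, df_den, lower.tail = FALSE),
       ges = ss_num / (ss_num + total_error_ss))
}

#' Paired t contrast on subject cell means
#'
#' Collapses each subject's data to a mean per level of `factor_col`
#' (optionally within a slice of subjects) and runs a paired t test
#' between two levels.
#'
#' @param data Long data frame.
#' @param dv,subject,factor_col Column names.
#' @param level_a,level_b The two levels to contrast (`a - b`).
#' @param subjects Optional subject ids to slice on.
#' @return List with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_contrast <- function(data, dv, subject, factor_col, level_a, level_b,
                            subjects = NULL) {
  if (!is.null(subjects)) data <- data[data[[subject]] %in% subjects, , drop = FALSE]
  if (nrow(data) == 0) stop("empty slice")
  a <- stats::aggregate(data[[dv]][data[[factor_col]] == level_a],
                        by = list(data[[subject]][data[[factor_col]] == level_a]), mean)
  b <- stats::aggregate(data[[dv]][data[[factor_col]] == level_b],
                        by = list(data[[subject]][data[[factor_col]] == level_b]), mean)
  mrg <- merge(a, b, by = "Group.1")
  if (nrow(mrg) < 2) stop("need at least 2 subjects for a paired contrast")
  tt <- stats::t.test(mrg$x.x, mrg$x.y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_diff = unname(tt$estimate))
}

#' Simple two-way within-subject interaction in one between group
#'
#' Tests the interaction of two within factors inside a single
#' between-subjects group, using the omnibus model's pooled error stratum
#' for that interaction (so the denominator df match the full design, the
#' usual convention for simple interaction follow-ups).
#'
#' @inheritParams mixed_anova
#' @param pair Character vector of the two within factors whose simple
#'   interaction is tested.
#' @param group Level of `between` defining the slice.
#' @return List with `F`, `df_num`, `df_den`, `p`, `ss`.
#' @export
simple_interaction <- function(data, dv, subject, within, pair, between,
                               group, flex_coding = c("linear", "categorical")) {
  stopifnot(length(pair) == 2, all(pair %in% within))
  eng <- vf_anova_engine(data, dv, subject, within, between, flex_coding)
  idx <- which(vapply(eng$subsets, function(s) {
    setequal(eng$within[s], pair)
  }, logical(1)))
  st <- eng$strata[[idx]]
  d <- ncol(st$Z)
  Xfull <- cbind(matrix(1, eng$N, 1), eng$X1)
  rss_err <- rss_fit(st$Z, Xfull)
  df_err <- d * (eng$N - 1 - eng$p_between)
  in_group <- eng$group == group
  if (sum(in_group) < 2) stop("fewer than 2 subjects in the sliced group")
  zg <- st$Z[in_group, , drop = FALSE]
  ss <- sum(colMeans(zg)^2) * sum(in_group)
  F <- (ss / d) / (rss_err / df_err)
  list(F = F, df_num = d, df_den = df_err,
       p = stats::pf(F, d, df_err, lower.tail = FALSE), ss = ss)
}
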