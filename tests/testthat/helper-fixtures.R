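# Shared fixtures built in code at test time.

# A small deterministic cohort reused by several test files.
small_cohort <- local({
  coh <- NULL
  function() {
    if (is.null(coh)) coh <<- generate_cohort(cohort_spec(n_subjects = 12, seed = 101))
    coh
  }
})

# Trial table with exact cell means: one trial per congruency cell.
two_cell_trials <- function(congruent_rt, incongruent_rt, condition = "LELS") {
  data.frame(condition = condition, trial_index = 1:2,
             congruency = c("congruent", "incongruent"),
             rt_ms = c(congruent_rt, incongruent_rt),
             correct = c(TRUE, TRUE), stringsAsFactors = FALSE)
}

# Balanced toy mixed design: `nw` two-level within factors crossed with a
# balanced two-level between group.
toy_mixed_design <- function(n_subjects = 12, effects = list(), seed = 1) {
  set.seed(seed)
  subj <- sprintf("s%02d", seq_len(n_subjects))
  d <- expand.grid(subject = subj, A = c("a1", "a2"), B = c("b1", "b2"),
                   stringsAsFactors = FALSE)
  d$g <- rep(c("g1", "g2"), each = n_subjects / 2)[match(d$subject, subj)]
  d$y <- rnorm(nrow(d))
  for (eff in names(effects)) {
    d$y <- d$y + effects[[eff]] * switch(eff,
      A = (d$A == "a2"),
      B = (d$B == "b2"),
      g = (d$g == "g2"),
      AB = (d$A == "a2") * (d$B == "b2"),
      gA = (d$g == "g2") * (d$A == "a2"))
  }
  d
}

expect_no_adjacency_violation <- function(ord) {
  adj <- function(a, b) abs(match(a, ord) - match(b, ord)) == 1
  expect_false(adj("HELS", "HEHS"))
  expect_false(adj("LEHS", "HEHS"))
}
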