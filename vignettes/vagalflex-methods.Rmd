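---
title: "Vagal flexibility and performance stability: models, simulation design, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vagal flexibility and performance stability: models, simulation design, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vagalflex)
```

## The scientific question and the measurement chain

Resting vagally mediated heart rate variability (HRV) is commonly read as
a trait index of self-regulatory capacity. The hypothesis this package
operationalizes is mediational: resting vagal tone should express itself
behaviorally *through* vagal flexibility — the degree to which phasic
vagal responses differ across distractor contexts — and flexible vagal
regulation should in turn keep cognitive inhibition stable across those
contexts. Three constructs carry the chain:

- **Resting lnRMSSD**: RMSSD over a 5 min rest baseline, log transformed.
- **Vagal flexibility (`Reactivity_SD`)**: each of four socioemotional
  Stroop conditions has its own 2 min baseline; reactivity is
  `task − baseline` RMSSD, and flexibility is the SD of the four
  reactivity scores. The SD — an intraindividual-variability (IIV)
  statistic — is the point: a subject who suppresses RMSSD in one
  condition and raises it in another is flexible even if the mean shift
  is zero, which is exactly what a mean-reactivity metric misses.
- **Performance stability (`Interference_SD`)**: Stroop interference
  (incongruent − congruent mean RT) per condition; its SD across the four
  conditions, with lower values meaning more stable inhibition.

Inference mirrors standard practice in this literature: Pearson and
partial correlations (covariates sex, age, BMI, and an HF-peak
respiration proxy matched to each HRV metric) with Fisher-z intervals;
the product-of-coefficients mediation with a normal-theory Monte Carlo
test of `a·b`; mixed ANOVAs with generalized eta squared; and a
simulation power analysis for the indirect effect.

## HRV computation

RR artifact correction flags intervals deviating more than 250 ms
(configurable) from an 11-beat running median and replaces them by cubic
spline interpolation over the surrounding clean beats. The window/threshold
pair behaves like the strong correction level of common HRV software on
the kinds of errors we simulate (missed/extra beats); corrected counts are
reported so a user can confirm the fraction stays well under 1%. A series
in which more than half the beats are flagged is refused rather than
"corrected".

Spectral analysis interpolates the tachogram to an evenly sampled signal
at 4 Hz (cubic spline), removes a linear trend, and fits an AR(16) model
by Burg recursion (`stats::ar.burg`). The one-sided parametric density is
evaluated on a 0.001 Hz grid; HF power is the trapezoidal integral over
0.15–0.4 Hz and HF-peak the grid argmax in the band. The choices — 4 Hz,
order 16, linear detrending only, absolute ms² units — are the common
defaults in HRV practice; none is critical for the pipeline's conclusions,
and the tests verify two invariances that matter more than any default:
the AR peak agrees with a nonparametric periodogram oracle, and the total
integrated density matches the signal variance within 15% (Parseval).
RMSSD needs none of this machinery and is computed directly from the
(corrected) intervals; a <60 s segment or a constant series is refused
for spectral analysis rather than silently producing a degenerate fit.

The log transform of skewed metrics is gated, not automatic: a variable
is logged only when Shapiro–Wilk rejects normality at α = 0.05 *and* the
sample skewness is positive, and the decision is recorded. Zero-spread
subjects would make `ln(Reactivity_SD)` undefined, so SDs are floored at
0.01 ms before the log, with a warning.

## The synthetic cohort: what it emulates and what it does not

The study design the generator reproduces: a 5 min rest baseline; four
conditions (LELS, HELS, LEHS, HEHS — low/high emotion crossed with
low/high social distractor content) in a counterbalanced order in which
the two high-emotion conditions are never adjacent and the two
high-social conditions are never adjacent (exactly 4 of the 24
permutations survive; sampling is uniform over them by rejection); per
condition a 2 min baseline, a task segment, and 64 Stroop trials (32 per
congruency, 5 s response deadline; censored trials get a missing RT and
count as errors).

Latent structure. Per subject, `T ~ N(0,1)` (resting vagal trait),
`F = a·T + e_m` (flexibility), `S = b·F + c'·T + e_y` (interference
*instability*); residual SDs default to the values that standardize F and
S. Defaults a = 0.65, b = −0.40, c' = 0 produce the full-mediation regime
the pipeline is designed to detect; the power-analysis conventions
(a = b = 0.4) are kept separately in the power module.

Observable mappings (constants in `vf_constants()`, chosen once to match
the descriptive scales of a healthy young-adult cohort and then frozen):

- resting RMSSD target `exp(3.88 + 0.45·T)` ms, so resting lnRMSSD is
  ~N(3.88, 0.45) plus measurement error;
- reactivity spread `exp(2.33 + 0.60·F)` ms, realized as a *fixed*
  zero-mean, unit-SD pattern over the four session positions scaled by
  the spread, plus an independent subject-level mean-reactivity draw
  (N(1.2, 8) ms). A fixed pattern rather than i.i.d. per-condition draws
  keeps the measured four-score SD equal to the intended spread instead
  of a chi-distributed multiple of it — without this the SD estimate from
  only four conditions is so noisy that no finite cohort could recover
  path b;
- interference spread `100 + 45·S` ms (linear, clamped at [4, 450],
  because the analysis models `Interference_SD` untransformed and a
  log-linear map would cap the recoverable standardized slope at ~0.37
  through pure nonlinearity), again via a fixed orthogonal pattern, plus
  a subject-level interference offset (SD 70 ms) that widens
  between-subject mean interference to realistic levels and cancels out
  of the four-condition SD;
- IBI level ~N(840, 120) ms per subject; respiratory frequency
  ~N(0.25, 0.05) Hz clamped inside the HF band, shifted +0.035 Hz during
  tasks; emotion distraction adds `60·(1 − Φ(F))` ms of extra
  interference in high-emotion conditions, so low-flexibility subjects
  show the stronger emotional-distraction pattern.

The IBI generator itself is additive: mean level + respiratory sinusoid +
AR(1) noise (φ = 0.3), with the sinusoid amplitude and the noise scale
jointly calibrated so the expected RMSSD equals the requested
`vagal_tone` in ms (the closed-form successive-difference RMS of a
sinusoid and of AR(1) noise make this a two-line calculation). An
integral-pulse-frequency-modulation model would be more physiological,
but the pipeline consumes IBIs, not ECG, and the additive model already
gives RMSSD and HF-peak the controllability the tests need. RTs are
ex-Gaussian (μ = 790, σ = 50, τ = 130 ms at default).

What the generator does *not* emulate — and hence what passing tests do
not show about real data: nonstationary drift within segments, ectopy and
true recording artifacts beyond simple missed/extra beats,
respiration–RSA amplitude coupling, RT sequential effects
(post-error slowing, practice), and any dependence of accuracy on the
latent traits. Parameter-recovery results therefore speak to the
*statistical* machinery, not to the field validity of the constructs.

## Numerical and design choices in the statistics

- **IIV summaries** use the sample SD (n−1), the behavioral-science
  convention; a population-SD option exists for sensitivity checks.
- **Outlier screen**: one pass, per named variable (`Interference_SD`,
  `ln Reactivity_SD`), strict `|z| > 3` computed on the full sample;
  z-scores are logged per exclusion.
- **Tertile split** is rank-based with stable tie-breaking; low and high
  take `round(n/3)` each, so 47 subjects split 16/15/16.
- **Mediation**: OLS with intercept; covariates {age, BMI, sex, resting
  HF-peak} in all three models; coefficients are reported unstandardized.
  The Monte Carlo test draws a* and b* independently (they come from
  different fitted models, so no covariance term), forms 10,000 products,
  and uses the percentile interval; `p = 2·min(P(ab ≤ 0), P(ab ≥ 0))`.
  Classification: *full* when c is significant, the indirect CI excludes
  zero, and c' is not significant; *partial* when all three are
  significant; *none* otherwise. Two-tailed α = 0.05 throughout, no
  multiplicity correction — matching the practice the pipeline models.
- **Mixed ANOVA** uses the classical univariate stratum decomposition on
  subject cell means: each within effect is projected onto an orthonormal
  contrast basis, and within each stratum the effect, its interaction
  with the between term, and the effect-by-subject error are computed by
  Type-III-style model comparisons. The flexibility term is entered as a
  single-df linear trend over tertile scores by default — with 47
  subjects that yields the (1, 45) denominator pattern characteristic of
  published analyses of this design — with a sum-contrast categorical
  option exposed. `ηG² = SS_effect / (SS_effect + Σ all error SS)`.
  Simple two-way interactions inside a flexibility group reuse the
  omnibus pooled error stratum, the usual follow-up convention.
- **Power analysis**: data are drawn from the standardized trivariate
  model; per replicate the indirect effect is tested by one of three
  constructs. The Monte-Carlo-CI and joint-regression tests — the tests
  one would actually run on data — require n ≈ 66 for 0.8 power at
  a = b = 0.4. The *joint-correlation* construct (both bivariate path
  correlations individually significant) reaches 0.8 power at n ≈ 59;
  this is the construct implemented by the analytic mediation
  sample-size calculators used for study planning, so the package uses it
  when reproducing planning-stage numbers and reports the conservative
  alternatives alongside (`analysis/05_power.R`). The gap is systematic,
  not simulation noise: the correlation test ignores the variance added
  by the partialled predictor and treats each path at df = n − 2.
- **Determinism**: every stochastic routine takes a seed; `required_n`
  derives one seed per candidate n so the bisection path cannot change
  any candidate's power estimate.

## Problem sizes used by the test suite

The stochastic suites run at sizes chosen to keep Monte Carlo error well
inside the asserted tolerances: parameter recovery uses 20 replicate
cohorts of 300 subjects (asserting mean recovered paths within ±0.1 and
the full-mediation classification in ≥80% of replicates); type-I control
uses 500 null cohorts of 100 subjects (asserting ≤7% false positives for
the indirect effect); the Monte Carlo CI is checked against a 10⁷-draw
brute-force oracle at ±0.01; the power analysis uses 10,000 replicates
per candidate n. Expected end-to-end recovery at these settings is
slightly attenuated (mean â ≈ 0.60, b̂ ≈ −0.35 against 0.65/−0.40)
because the measured variables carry measurement error and the
interference-SD map is weakly nonlinear at its clamps; both biases are
well inside the asserted band and are properties of the *measurement*
chain, not the estimator.

## Known limitations

- The AR spectral estimate is parametric; with very short segments or
  near-constant series it refuses to fit rather than degrade gracefully.
- The generator's latent-to-observable maps are linear (one
  intentionally log-linear) with fixed condition patterns; real IIV
  structure is richer, and recovered paths inherit the attenuation noted
  above.
- Mediation is single-mediator OLS with a normal-approximation Monte
  Carlo test; no bootstrap, multilevel, or SEM machinery.
- The ANOVA engine requires complete within-subject cells (cell means);
  unbalanced *within* data must be aggregated or imputed upstream, and
  only one between-subjects term is supported.
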