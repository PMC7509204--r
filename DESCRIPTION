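Package: vagalflex
Title: Vagal Flexibility, Heart Rate Variability Reactivity, and Cognitive
    Performance Stability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for studying vagal flexibility: computes
    time-domain (RMSSD) and autoregressive spectral (HF power, HF peak
    frequency) heart rate variability metrics from interbeat-interval
    series, derives per-condition vagal reactivity and Stroop interference
    scores and their intraindividual-variability summaries, and tests the
    mediation chain from resting vagal tone through vagal flexibility to
    performance stability with product-of-coefficients Monte Carlo
    inference, mixed-design ANOVA with generalized eta squared, and
    simulation-based power analysis for the indirect effect. Includes a
    synthetic-cohort generator with a known latent mediation structure so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
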