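Package: memrep
Title: Representational Similarity Analysis of Autobiographical Memory
    Consolidation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for measuring the time-dependent strength of
    individual autobiographical-memory representations in ventromedial
    prefrontal cortex with representational similarity analysis (RSA).
    Covers trial-wise GLM pattern estimation with multivariate noise
    normalisation, within-minus-between "neural representation" scoring
    across scanning sessions, group inference (one-sample t tests,
    repeated-measures ANOVA with Mauchly/Greenhouse-Geisser handling,
    Bonferroni post hocs, Cousineau within-subject error bars, interrater
    ICC), a longitudinal prediction-shift test for an eight-month follow-up,
    and an ROI-constrained searchlight with sign-flip permutation
    cluster-level family-wise error inference. A synthetic-cohort generator
    emulating the 12-session/96-trial longitudinal design makes every stage
    testable end to end without any scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
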