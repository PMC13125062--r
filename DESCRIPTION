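Package: sfgap
Title: Individualized Structure-Function Coupling and the Structure-Function Gap
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Predicts white-matter microstructural integrity (fractional
    anisotropy, FA) from distributed resting-state functional connectivity
    (FC) with Gaussian-process regression using automatic relevance
    determination (ARD), under subject-level cross-validation with
    mixed-effects confound removal. Provides inverse-lengthscale feature
    importance maps, tract-level clustering of importance patterns via a
    low-dimensional embedding and PERMANOVA, per-region structure-function
    gap residuals, and regularized canonical correlation analysis linking
    gaps to behavioral batteries with permutation inference. Includes a
    longitudinal synthetic cohort generator with planted ground truth so
    every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    ranger,
    e1071,
    nnet,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    lmerTest,
    vegan,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
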