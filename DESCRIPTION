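Package: trajmix
Title: Latent Trajectory Analysis of Longitudinal Clinical Outcomes by
    Growth Mixture Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits mixtures of latent growth curve models (growth curve
    models, group-based trajectory models, latent class growth analysis,
    and growth mixture models with class-invariant or class-variant random
    effects) to long-format longitudinal outcome data by full-information
    maximum likelihood under missing-at-random assessments.  Implements a
    systematic four-stage model-building and selection strategy (class
    enumeration by BIC, scaled entropy, average posterior probability of
    assignment, and a parametric bootstrap likelihood ratio test, followed
    by residual-variance relaxation, random-effect addition, and Wald-based
    polynomial pruning), manual 3-step covariate and distal-outcome
    analysis with fixed misclassification logits, cross-trajectory risk
    ratios, clinical remission and recovery endpoint derivation, and a
    synthetic cohort generator emulating 2-year first-episode-psychosis
    follow-up studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    numDeriv,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    mvtnorm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
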