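Package: tbtprog
Title: Trabecular Bone Texture Descriptors and Prediction of Radiographic
    Knee Osteoarthritis Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying radiographic knee osteoarthritis (KOA)
    progression from trabecular bone texture (TBT). Provides directional
    multi-scale Hurst-exponent descriptors of tibial subchondral bone
    computed with the quadratic-variations estimator over an automatically
    placed 16-region grid, longitudinal delta features, scenario-based
    joint-space-narrowing progression outcomes with index-knee selection,
    and an 18-model logistic-regression evaluation framework with
    stepwise-AIC feature selection, repeated stratified cross-validation
    and paired (DeLong) ROC comparison. Includes exact fractional Brownian
    motion and fractional Brownian sheet simulators and a longitudinal
    cohort simulator with calibrated progressor prevalence, so the whole
    pipeline can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    pROC,
    tiff,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
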