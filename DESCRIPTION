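Package: hnplanr
Title: Automated Head-and-Neck IMRT Template Planning, Dose Evaluation and
    Commissioning at Desk Scale
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying automated head-and-neck intensity-modulated
    radiotherapy (IMRT) planning workflows without clinical data. Provides a
    synthetic anthropomorphic phantom generator (CT-like volume plus the ten
    structures modelled in bilateral head-and-neck planning), template-plan
    automation (isocenter placement, 9-beam gantry layout, per-beam collimator
    jaw fitting), beam's-eye-view anatomical projections on the fluence-map
    grid, a pluggable fluence-map predictor with six parotid/target tradeoff
    profiles and a deterministic conformal baseline, a simplified forward dose
    engine with prescription normalization, dose-volume histogram and
    conformity/heterogeneity endpoint evaluation, gamma-index quality
    assurance, and the paired Wilcoxon signed-rank commissioning analysis with
    Bonferroni correction and DVH band aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
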