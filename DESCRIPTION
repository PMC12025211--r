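Package: ctbalance
Title: Bayesian-Optimised Class-Imbalance Correction for CT Body-Composition Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for training and evaluating class-imbalance-aware deep
    learning pipelines on axial abdominal CT: detection of the minority L3
    vertebral slice and multi-class segmentation of skeletal muscle,
    subcutaneous and visceral adipose tissue. Class-imbalance correction is
    expressed through two correction design variables (a minority
    augmentation ratio and constrained per-class loss weights) that are
    optimised jointly with the usual training hyperparameters by Bayesian
    optimisation (Gaussian-process surrogate with expected-improvement
    acquisition) of the inverse F1 score. Includes Hounsfield-unit
    preprocessing and range-based mask refinement, Dice / Jaccard / mean
    surface distance / Bland-Altman evaluation, a synthetic abdominal CT
    phantom generator for end-to-end testing without clinical data, and
    small CPU-scale residual-CNN and U-Net reference backbones behind a
    pluggable trainer contract.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lhs,
    RNifti,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
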