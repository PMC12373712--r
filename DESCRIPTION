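Package: slmvpa
Title: Searchlight Multivoxel Pattern Analysis of Simulated Motion-Extrapolation fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates interception-paradigm fMRI experiments (visible and
    occluded motion, high- and low-predictability contexts) with planted
    multivoxel condition patterns, estimates condition-wise and single-trial
    (least-squares-separate) GLM betas with canonical HRF regressors and
    their temporal and dispersion derivatives, runs ROI-restricted
    searchlight decoding with a shrinkage-regularized linear discriminant
    classifier under balanced leave-25%-trials-out partitioning, and performs
    selection-plus-permutation group inference: a chance-level cutoff,
    top-5% informative-sphere selection, within-run label-permutation nulls,
    a group-level permutation p-value, sphere-center overlap across
    analyses, and trial-history (CC/CI/IC/II) repeated-measures contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    RNifti,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    withr
Config/testthat/edition: 3
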