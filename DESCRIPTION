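Package: sessm
Title: Simon-Effect Sequential Sampling Model Fitting and Model-Based fMRI
    Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits the Simon-effect sequential sampling model (SE-SSM), a
    drift-diffusion model extended with a conflict-induced starting-point
    bias and a within-trial conflict-counteraction drift gain, to choice
    and response-time data from spatial conflict tasks. Likelihoods are
    computed by propagating a discretized decision-variable distribution
    through transition matrices with absorbing decision bounds. Includes
    multi-restart maximum-likelihood estimation with two-resolution
    refinement, AIC/wAIC model comparison across the nested candidate
    family M1-M4, reconstruction of the expected decision variable for
    response-locked BOLD regressors, first-level GLM construction with a
    canonical double-gamma hemodynamic response, and across-subject
    parameter-map correlation tests with threshold-free cluster
    enhancement and maximal-statistic permutation family-wise error
    control. A synthetic-data generator reproduces the behavioral and
    scan structure of a two-session Simon task study so the full pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
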