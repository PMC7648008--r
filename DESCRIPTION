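Package: regionmkl
Title: Atlas-Based Multiple Kernel Learning for Decoding fMRI Contrast Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Whole-brain multivariate decoding of functional MRI contrast
    images using one linear kernel per anatomical atlas region and a sparse
    multiple kernel learning (SimpleMKL) machine that jointly learns
    simplex-constrained region weights and a support vector classifier or
    epsilon-insensitive regressor. Includes a first-level general linear
    model with a canonical haemodynamic response function and discrete
    cosine drift basis, kernel normalisation and mean centering with strict
    train/test hygiene, nested cross-validation (leave-one-subject-out and
    k-fold) with permutation inference, region ranking and voxel weight
    back-projection, stimulus picture metrics, and a synthetic-data module
    that emulates a blocked threat-perception study design so the whole
    pipeline is testable without access to scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    png,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    kernlab,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
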