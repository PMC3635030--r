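Package: connsvm
Title: Functional Connectome Classification and Age Prediction with
    Support Vector Machines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds per-scan resting-state functional connectomes (Fisher-z
    transformed pairwise Pearson correlations between spherical regions of
    interest), selects connectivity features per cross-validation fold by
    univariate t-test or correlation filtering, classifies age group with
    soft-margin support vector machines (linear and Gaussian kernels,
    binary and Weston-Watkins multiclass) and predicts continuous age with
    epsilon-insensitive support vector regression.  Cross-validation is
    grouped by subject (all scans of a subject leave together) with exact
    binomial significance testing, holdout grid-search parameter tuning,
    consensus-feature and node-importance summaries, and BrainNet Viewer
    export.  Includes a synthetic cohort generator with planted age effects
    so the full pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    Matrix,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    kernlab,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
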