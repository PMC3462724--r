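Package: restfc
Title: Discriminative Analysis of Resting-State Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-brain resting-state functional-connectivity discrimination
    between two subject groups. Builds per-subject edge-feature vectors from
    regional time series (linear detrend, ideal band-pass filtering, nuisance
    regression, Pearson correlation, Fisher z-transform, upper-triangle
    vectorization), ranks edges by a cross-group Kendall tau coefficient,
    classifies subjects with PCA followed by a soft-margin linear SVM under
    leave-one-out cross-validation, assesses significance by label permutation,
    and back-projects classifier weights into discriminative edge and region
    weights. Includes a seeded multivariate-normal cohort simulator with
    planted edge-level group differences for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    MASS,
    e1071,
    jsonlite,
    tools,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
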