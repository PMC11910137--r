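Package: scrstax
Title: Taxonomy Identification from Single-Cell Raman Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking machine-learning pipelines that identify
    bacterial taxonomy from single-cell Raman spectroscopy (SCRS) data.
    Provides spectral preprocessing (background subtraction, Savitzky-Golay
    smoothing, asymmetric-least-squares baseline correction, normalization),
    six dimensionality-reduction methods and ten classifiers behind uniform
    interfaces, stratified 10-fold evaluation with nested grid-search
    cross-validation, a two-step growth-stage-then-taxonomy classifier
    ensemble, Bayesian (BEST) comparison of model accuracies with FDR
    control, a genus-level reference-extension procedure for environmental
    samples, and a synthetic SCRS generator that emulates a multi-strain,
    multi-growth-stage reference library for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    Matrix,
    class,
    e1071,
    kernlab,
    nnet,
    randomForest,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
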