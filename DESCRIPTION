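Package: eegThreeWay
Title: EEG Regularity Analysis with Wavelet Sample Entropy and Three-Way
    Covering Classification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A three-stage pipeline for classifying multichannel EEG
    recordings by signal regularity: a three-level discrete wavelet
    decomposition (Mallat pyramid) isolates the low-frequency
    approximation band, per-channel sample entropy quantifies the
    regularity of that band, and a three-way-decision classifier built
    on the optimal-center constructive covering algorithm assigns each
    subject to a positive, negative, or boundary (abstain) region.
    Includes approximate entropy, a plain periodogram, stratified
    k-fold cross-validation with accuracy/error/boundary metrics,
    adapters for standard binary baselines, and a reproducible
    synthetic EEG cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    e1071,
    class,
    randomForest,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Classification, TimeCourse, Preprocessing
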