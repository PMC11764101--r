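Package: mistack
Title: Multi-Domain Feature Rotation and Stacking Ensembles for Motor
    Imagery EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Decoding of binary motor-imagery tasks from epoched
    multichannel EEG. Extracts features from four domains (time-domain
    statistics including Higuchi's fractal dimension; band power spectral
    density and energy; discrete-wavelet sub-band energies; filter-bank
    common spatial patterns), selects significant features per domain by
    recursive feature elimination with random-forest importance, enriches
    them by a local PCA rotation transformation with composite fusion, and
    classifies with a two-layer stacking ensemble whose meta-classifier
    receives per-domain class probabilities supplemented by a linear
    discriminant projection of the pooled significant features. Includes a
    synthetic generator of ERD/ERS-structured motor-imagery EEG, repeated
    stratified cross-validation, and per-domain contribution analysis of
    the meta-classifier weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    nnet,
    randomForest,
    signal,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
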