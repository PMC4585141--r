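Package: sourcetract
Title: Source-Tract Voice Deconstruction and Gender-Dependent Speaker Verification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sample-adaptive deconstruction of running speech into orthogonal
    glottal-source and vocal-tract estimates via a lip-radiation compensation
    stage, an adaptive PARCOR prediction-error lattice and lattice-ladder
    joint-process estimation, together with the full gender-dependent
    extended-biometric speaker-verification stack built on it: a synthetic
    voice-corpus generator (glottal pulse train times all-pole tract times
    radiation), an MFCC front-end with energy, pitch and third-formant extras
    plus cepstral mean subtraction, feature warping and RASTA filtering,
    diagonal-covariance GMM-UBM modelling with MAP mean adaptation and
    Z/T/ZT score normalisation, and EER/HTER/HEER evaluation with DET curves
    and a two-layer bootstrap standard error.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    signal,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
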