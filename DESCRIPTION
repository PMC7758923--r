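Package: pgesdetect
Title: Automatic Detection of the End of Postictal Generalized EEG Suppression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting the end of postictal generalized EEG
    suppression (PGES) after generalized tonic-clonic seizures. Provides
    EDF and plain-text EEG readers, bipolar montage derivation, polyphase
    resampling to a common rate, Hann-window denoising, sliding-window
    crop extraction with latency-aware labeling, two detector families (a
    compact EEGNet-style convolutional network trained on raw crops, and
    tree ensembles on spectral/fractal/entropy features), continuous
    100 ms inference producing probability traces, onset calling, and
    latency-aware cohort evaluation. A seeded simulator of post-seizure
    EEG with a suppression phase, intermittent slow-wave activity and
    configurable artifacts makes the whole pipeline testable without
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    signal,
    ranger,
    xgboost,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
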