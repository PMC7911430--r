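Package: bovocal
Title: Acoustic Monitoring and Behavioral Classification of Cattle Vocalizations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for decibel-triggered capture of cattle vocalizations from
    barn sound sensors, with multi-sensor zone deduplication, short-time Fourier
    transform (STFT) spectral-gating noise removal with smoothed time-frequency
    masks, Mel-frequency cepstral coefficient (MFCC) feature extraction, and two
    convolutional neural networks trained with a from-scratch Adadelta optimizer:
    a binary cattle-voice/noise gate and a four-class behavioral classifier
    (estrus, food anticipation, cough, normal). Includes confusion-matrix
    evaluation utilities, a synthetic cattle-call/farm-noise generator for
    end-to-end testing without field recordings, and a command-line monitoring
    pipeline that emits per-event JSON/CSV reports.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
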