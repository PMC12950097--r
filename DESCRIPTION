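Package: swallowseg
Title: Automated Detection and Segmentation of Swallow Sounds from
    Cervical Auscultation Audio
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and temporally segments swallow sounds in cervical
    auscultation recordings of preterm neonates during feeding. Audio is
    resampled to 16 kHz, split into 0.96 s frames with 50% overlap, and
    converted to log-Mel spectrogram patches plus a zero-crossing rate;
    frames are mapped to fixed-length embeddings and a fully-connected
    detection head emits six sigmoid confidences per frame, one per
    0.16 s subframe, giving 0.16 s temporal resolution after fusing
    overlapping frames and thresholding at 0.5. Includes interval
    decoding, diagnostic test accuracy evaluation (sensitivity,
    specificity, PPV, NPV, F1) stratified by feeding type, and a
    synthetic labeled feeding-audio generator so the full pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
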