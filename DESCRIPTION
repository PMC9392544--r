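Package: eegresp
Title: CNN-LSTM Classification of rTMS Treatment Response from Resting-State EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Pipeline for classifying treatment response to repetitive
    transcranial magnetic stimulation (rTMS) from 19-channel resting-state
    EEG. Covers preprocessing (ICA artifact rejection, 50 Hz notch and
    0.1-60 Hz band-pass filtering, fixed-length segmentation), training-set
    augmentation by random same-class averaging, a 1D convolutional LSTM
    network trained with Adam in compiled code, and stratified 10-fold
    cross-validated evaluation (sensitivity, specificity, accuracy,
    Cohen's kappa, ROC-AUC). Includes a synthetic-cohort generator with
    configurable class-conditional spectral effects and realistic blink,
    muscle, line-noise and drift artifacts, plus a minimal EDF writer and
    reader, so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
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
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
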