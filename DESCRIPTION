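Package: errpdetect
Title: Event-Locked and Asynchronous Detection of Error-Related Potentials in Continuous-Feedback EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for error-related potentials (ErrPs) recorded
    during tasks with continuous visual feedback. Provides a synthetic-data
    generator for multichannel EEG sessions with injected execution- and
    outcome-error responses, EDF and tabular event input/output, signal
    conditioning (band-pass and notch filtering, EOG artifact regression,
    common-average referencing), Welch and Burg power-spectrum estimation,
    event-locked linear-SVM classification with permutation significance
    testing and severity contrasts, an asynchronous sliding-window detector
    with R-squared feature selection, Platt probability calibration and
    temporal smoothing, and performance evaluation via threshold-sweep
    ROC/AUC and positive/negative seconds rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    e1071,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
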