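Package: klsmm
Title: Support Matrix Machines with Model-Parameter Transfer for Matrix-Form EEG Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Binary classification of matrix-form trials (e.g. band-power features of
    motor-imagery EEG) with the support matrix machine: a hinge-loss classifier whose
    regression coefficient is a matrix regularized by the spectral elastic net (squared
    Frobenius norm plus nuclear norm), fitted by ADMM with singular value thresholding
    and an SMO-style box-constrained dual quadratic program. A knowledge-leverage
    extension regularizes the target model toward a source subject's fitted coefficient
    matrix, transferring model parameters (never raw data) when few labeled target
    trials are available. Includes a CSP/band-power EEG feature front-end, vectorized
    linear SVM and adaptive-SVM baselines, synthetic transfer-task and EEG generators,
    cross-validated model selection, and evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
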