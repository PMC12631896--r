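Package: mifuse
Title: Cross-Subject Hybrid EEG-fNIRS Motor-Imagery Decoding with
    Wasserstein-Guided Transfer Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A decoding framework for hybrid electroencephalography (EEG)
    and functional near-infrared spectroscopy (fNIRS) motor-imagery
    brain-computer interfaces. Provides modality-specific depthwise-separable
    convolutional base networks trained by backpropagation, Wasserstein
    trusted-score source-domain selection, deep correlation-alignment (CORAL)
    and deep canonical-correlation (DCCA) transfer losses, accuracy-weighted
    multimodal feature fusion, stratified cross-validated evaluation with a
    Friedman omnibus test, and a synthetic motor-imagery paradigm simulator
    with planted event-related desynchronization and hemodynamic responses so
    the whole pipeline is testable without any recorded data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
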