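Package: cardiosift
Title: Single-Lead ECG Beat Classification with Multi-Transform Features
    and Red-Fox Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully seeded pipeline for normal-versus-anomalous
    classification of single-lead electrocardiogram (ECG) beats. Includes a
    synthetic ECG generator with ground-truth R-peaks and standard noise
    sources (powerline, baseline wander, muscle artifact, electrode motion);
    integer-coefficient band-pass filtering and adaptive dual-threshold QRS
    detection with 600 ms beat segmentation; per-beat features from a
    fractional discrete cosine transform, Radon projections of a wavelet
    scalogram, and a fractional-wavelet decomposition; red-fox-optimization
    wrapper feature selection; random oversampling with inverse-count class
    weights; and a compact one-dimensional convolutional network ("i-AlexNet")
    trained with stochastic gradient descent plus momentum. Readers for WFDB
    and CSV signals are provided so the same pipeline runs on public
    arrhythmia databases or on synthetic records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
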