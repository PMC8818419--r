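Package: ecgflow
Title: ECG Heartbeat Classification with QRS Detection, Beat Screening and
    an RBF Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for binary (normal vs abnormal) heartbeat
    classification from single-lead electrocardiogram recordings. Provides a
    Pan-Tompkins QRS detector (integer-coefficient band-pass cascade,
    derivative, squaring, moving-window integration, adaptive dual-threshold
    peak search with search-back), R-anchored fixed-width beat truncation
    with physiological consistency filters, K-means (K = 2) outlier
    screening of truncated beats, covariance-matrix principal component
    reduction, and a Gaussian radial-basis-function network classifier with
    stratified k-fold cross-validation. Includes a seeded synthetic ECG
    generator (Gaussian P-QRS-T bump model with powerline, baseline-wander
    and white noise) so that every stage can be exercised without external
    data, plus readers and writers for WFDB format-212 record triplets and
    plain CSV records.
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
    optparse,
    yaml
Config/testthat/edition: 3
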