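Package: driftanchor
Title: Signal-Drift and Batch-Effect Correction for LC-MS Peak Tables
    Without Full QC Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for simulating liquid chromatography-mass spectrometry
    (LC-MS) peak-area tables with controllable signal drift and batch
    effects, detecting outliers from replicate-pairwise absolute
    differences, and correcting drift in batches that lack pooled
    quality-control (QC) injections.  A train/test procedure estimates
    "pseudoQC" anchor points from the variability of experimental samples:
    four parameters (quantile trimming band, number of batch segments,
    rolling-median window, and anchor offset) are grid-optimized against
    true QC samples in a training batch and transferred to the remaining
    batches, after which a QC-robust smoothing-spline correction is applied
    using the estimated anchors.  Also included are limit-of-detection
    filtering, sample-weight normalization, and evaluation metrics
    (cross-validated regression against a drift-free reference and the
    maximum QC distance in principal-component space).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    zoo,
    jsonlite,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
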