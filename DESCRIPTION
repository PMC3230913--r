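Package: arrayClean
Title: Spatial Artifact Detection and Correction for Affymetrix Probe-Level Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quality control for batches of high-density oligonucleotide
    microarrays. Detects spatial artifacts (scratches, salt streaks, bubbles,
    uneven hybridization) on each chip by iterative cross-chip variance
    scoring and sliding-window segmentation, normalizes probe intensities
    with an artifact-aware quantile scheme that excludes flagged probes from
    the reference distribution, and replaces artifact intensities with
    best-fit values from a multiplicative rank-1 probe-set model fitted by
    singular value decomposition inside an expectation-maximization loop.
    Includes a synthetic chip and artifact simulator, an evaluation harness
    (log-domain expression error, ROC/AUC for fold-change detection), CEL
    version-3 text input/output, and heat-map rendering of scores, masks and
    model residuals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    limma,
    withr
biocViews: Microarray, QualityControl, Preprocessing, OneChannel
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
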