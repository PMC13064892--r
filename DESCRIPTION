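Package: centroquant
Title: Quantification of Centromere Foci Dynamics in Fluorescence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Measurement machinery for centromere protein dynamics in
    single cells: simulation of multi-channel fluorescence fields with
    known ground truth, nuclear segmentation, Laplacian-of-Gaussian
    centromere focus detection on a reference (ACA) channel,
    background-adjusted per-focus and per-cell target intensity
    measurement, two-component Gaussian-mixture gating of nuclear EdU
    intensity for S-phase classification, mitosis-aligned time-lapse
    trace quantification, delta-delta-Ct qPCR fold changes, and
    replicate-average (superplot) statistics with Welch's t test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
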