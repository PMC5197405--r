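Package: bosig
Title: Border-Ownership Signal Analysis for Visual Cortex Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for measuring border-ownership
    selectivity of single neurons in primate visual cortex tested with
    natural scenes. Provides construction of the factorial stimulus sets
    (180-degree rotation about the receptive field, local color-contrast
    inversion, erfc-faded patches, and the counterbalanced square test),
    an inhomogeneous-Poisson generator of synthetic recordings, per-cell
    factorial models on Anscombe-transformed spike counts with Type II
    tests, population comparison of scene and square signals by orthogonal
    regression through the origin, cross-scene consistency estimation with
    Gaussian deconvolution of trial noise, and signal-latency estimation
    by two-phase regression on cumulative spike counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    jsonlite,
    stats,
    utils
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
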