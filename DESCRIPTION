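Package: qtapdiff
Title: Differential Interactomics for Quantitative Tandem Affinity
    Purification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-processing pipeline for label-free quantitative AP-MS
    (qTAP) experiments comparing a mock and a treatment condition.
    Reads MaxQuant-style proteinGroups tables, removes decoy and
    contaminant hits, log2-transforms intensities, applies a
    valid-value filter and replicate quality control, optionally
    normalizes every protein to the per-sample bait intensity (for
    degrading baits), imputes left-censored missing values from a
    down-shifted normal distribution, and calls condition-dependent
    interactors with an S0-moderated two-sample test controlled by a
    permutation-based false discovery rate.  A ground-truthed AP-MS
    simulator with intensity-dependent missingness makes the whole
    analysis testable without raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
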