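Package: spinemorph
Title: Dendritic Spine Morphometry, Plaque Proximity and Synaptic
    Quantification for 3-D Confocal Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying dendritic spine density and morphology,
    amyloid plaque proximity, fluorescence intensity and synaptic puncta
    colocalisation in calibrated multi-channel 3-D confocal image stacks,
    together with the matching statistical inference layer (linear
    mixed-effects group contrasts, repeated-measures correlation,
    spine-shape chi-square tests and delta-delta-Cq qPCR quantification).
    Includes a synthetic-data module that generates image stacks and
    hierarchical per-dendrite cohorts with known ground truth, so that
    every measurement stage can be validated by round-trip recovery.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    tiff,
    jsonlite,
    lme4,
    lmerTest,
    emmeans,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
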