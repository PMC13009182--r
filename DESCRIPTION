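Package: certasdial
Title: Detection of Certas Plus Shunt Valve Settings from CT Marker Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing pipeline that infers the dial setting of a Codman
    Certas Plus programmable cerebrospinal-fluid shunt valve from a CT scan in
    which the valve's five radiopaque markers have been segmented. Computes
    physical-space marker centroids from NIfTI label maps, constructs the valve
    plane and orientation frame, measures the signed indicator angle, and maps
    it onto the eight 45-degree setting zones. Includes a synthetic phantom
    generator with ground truth, a classical threshold-based fallback
    segmenter so the full pipeline runs without a trained network, and
    evaluation tools: per-label Dice and IoU, confusion matrices, exact and
    adjacent-setting accuracy with Clopper-Pearson exact binomial confidence
    intervals, and per-setting angle summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    igraph,
    jsonlite,
    withr,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
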