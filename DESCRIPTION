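Package: pirinv
Title: Concentration-Invariant Odor Coding Analysis for Two-Photon Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of two-photon calcium imaging of odor-evoked
    cortical activity: simulation of movies and trial-structured response data
    with known ground truth, automated cell segmentation by greedy correlation
    clustering of neighboring pixels with iterative pixel-weight estimation,
    fluorescence trace extraction with neuropil correction, delta-F/F
    computation, linear temporal deconvolution and run-length response
    detection, population-vector statistics (trial correlation matrices,
    lifetime sparseness, PCA), leave-one-out linear decoding of odor identity
    including a concentration-generalization task, nearest-neighbor-index
    spatial permutation tests, and per-cell ANOVA plus identity-shuffle
    bootstrap statistics for detecting concentration-invariant neurons.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    e1071,
    signal,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
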