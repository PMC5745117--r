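Package: RamanMSH
Title: Multimodal Spectral Histopathology for Residual Basal Cell
    Carcinoma Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computational pipeline for multimodal spectral histopathology
    (MSH) of skin tissue resected during basal cell carcinoma (BCC) surgery:
    adaptive intensity-threshold segmentation of tissue auto-fluorescence
    images, variance/area-weighted allocation of Raman sampling points,
    band-area spectral features and a neural-network tissue classifier, the
    two-round per-segment diagnosis procedure with nearest-neighbour
    splitting, and an exact binomial decision model that converts the
    number of BCC-labelled regions into a per-sample call. Includes seeded
    phantom and synthetic Raman spectrum generators so the full pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    Rcpp,
    nnet,
    withr,
    jsonlite,
    yaml,
    tiff,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
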