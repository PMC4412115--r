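Package: phenoscope
Title: Automated Phenotype Classification of Cyanobacterial Fluorescence Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies single cyanobacterial cells in RGB fluorescence
    micrographs into three pigmentation phenotypes: wild-type (red
    chlorophyll/phycocyanin fluorescence), ethanol-producer (orange, from
    phycocyanin down-regulation) and dead (unspecific green). Provides
    flat-field illumination correction against a blank image, maximum-entropy
    (Kapur) thresholding of the red and green channels, 8-connected particle
    registration with size and border filters, normalized hue-histogram plus
    mean-brightness features, and a one-hidden-layer feed-forward network
    trained by resilient propagation with a genetic-algorithm fallback.
    Includes a synthetic micrograph generator with ground truth, so the whole
    pipeline - including an in-silico reconstruction of a wild-type/producer
    mixing experiment - is testable without microscopy data, and utilities for
    bulk absorption spectra (normalization at 680 nm, phycocyanin/chlorophyll
    ratio).
License: MIT
Encoding: UTF-8
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    jsonlite,
    tiff,
    png,
    yaml,
    EBImage,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
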