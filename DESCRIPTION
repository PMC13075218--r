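Package: canopyn
Title: Canopy Nitrogen Diagnosis from Fused UAV Hyperspectral and LiDAR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the nitrogen status of orchard tree canopies by
    fusing UAV hyperspectral reflectance with LiDAR-derived structure. Implements
    full-spectrum normalized-difference spectral index (NDSI) band-pair screening,
    Savitzky-Golay smoothing, progressive-densification TIN ground filtering,
    canopy maxima modelling with marker-controlled watershed tree segmentation,
    3D convex-hull crown volume, and leave-one-out cross-validated comparison of
    multiple linear, partial least squares, support vector and random forest
    regression for canopy nitrogen concentration (CNC) and aboveground nitrogen
    accumulation (AGNA). A synthetic-data module simulates nitrogen-structured
    canopy spectra and tree point clouds so the whole chain is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    e1071,
    mixOmics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
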