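Package: phytostress
Title: Detecting the Type and Severity of Salt and Drought Stress in
    Plants from Image Texture, Physiological and miRNA Markers
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to predict the type (drought, salinity, or both) and
    severity (levels 0-3) of abiotic stress in crop plants from three
    feature families: gray-level co-occurrence matrix (GLCM) texture
    statistics of leaf images, physiological and biochemical assays, and
    leaf miRNA concentrations. Provides a full-factorial synthetic-data
    generator emulating a greenhouse stress experiment, leaf-image
    simulation and segmentation, epsilon support-vector regression with
    four kernels and an owned coordinate-descent solver, genetic-algorithm
    and particle-swarm tuning of the kernel parameter, five-fold
    cross-validation scoring by mean squared error and the coefficient of
    determination, and Banzhaf power-index feature importance with exact
    and Monte Carlo estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    readxl,
    stats,
    tools,
    utils,
    yaml,
    zip
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
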