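Package: treemort
Title: Tree-Level Drought Mortality Analysis on Synthetic Forest Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates forest landscapes (conical tree crowns on a canopy
    height model, four-band imagery with sunlit/shaded live/dead spectral
    classes, correlated environmental gradients, and a height-by-environment
    mortality process) and analyses them with a tree-level drought-mortality
    pipeline: treetop detection and watershed crown segmentation from the
    canopy height model, Gaussian maximum-likelihood pixel classification
    with crown dieback threshold calibration, survivor-pool mortality rates
    by height class, standardized logistic and binned-rate driver models
    with odds-ratio reporting, and inverse-variance-weighted meta-regression
    of the height-mortality slope against environmental gradients.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
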