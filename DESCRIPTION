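Package: lurkit
Title: Land Use Regression Modelling of Fine Particulate Matter
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building land use regression (LUR) exposure models of
    fine particulate matter (PM2.5) on a planar raster grid: circular-buffer
    focal statistics over land-use, greenness (NDVI) and distance layers,
    inverse-distance-weighted interpolation of station meteorology, assembly
    of station-month design matrices with a-priori effect directions,
    direction-constrained supervised stepwise regression with significance
    and variance-inflation gating, k-fold cross-validation, and gridded
    prediction surfaces with air-quality-guideline exceedance summaries.
    Includes a seeded synthetic-scene generator with a known ground-truth
    model so every stage of the pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
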