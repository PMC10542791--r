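Package: amazonagb
Title: Airborne LiDAR to Wall-to-Wall Aboveground Biomass Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for estimating tropical-forest aboveground
    biomass (AGB) from airborne laser scanning transects and extrapolating it
    to a wall-to-wall 250-m map from satellite covariates. Includes
    isolated-point outlier filtering on a voxel lattice, ground classification
    by progressive TIN densification, 1-m digital terrain and canopy height
    models, top-of-canopy height (TCH) aggregation, a TCH power-law biomass
    model, field-plot calibration and validation, random-forest raster
    extrapolation with variable importance, and three-level Monte Carlo
    uncertainty propagation. A synthetic-scene generator produces
    transect-scale forest scenes with complete ground truth (terrain, stems,
    point cloud, biomass, covariates) so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    RANN,
    ranger,
    minpack.lm,
    jsonlite,
    mgcv,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
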