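Package: canoheight
Title: Terrain Correction of LiDAR-Derived Forest Canopy Height
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies and corrects terrain-induced bias in forest canopy
    heights derived from airborne LiDAR point clouds. Conventional per-point
    normalization (subtracting a digital elevation model from each return)
    depresses heights on the upslope side of a tree and elevates them
    downslope by up to (d/2)tan(i) for crown diameter d and slope angle i.
    The package implements per-tree normalization instead: vegetation
    returns are grouped by crown polygon, each tree's base location is
    estimated as the height-weighted planimetric centre of gravity of its
    returns, and all of the crown's returns are renormalized against the
    single DEM elevation at that base. Supporting components include a
    synthetic LiDAR scene simulator with known ground truth, multiscale
    curvature ground classification, inverse-distance-weighted DEM/CHM
    gridding, local-maxima tree detection with marker-based watershed crown
    segmentation, plot-level height-difference statistics, and
    basal-area-weighted (Lorey's) stand height regression on height
    percentiles with K-fold stepwise selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    mgcv,
    jsonlite,
    stats,
    utils,
    graphics,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
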