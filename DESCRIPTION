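Package: borealdist
Title: Hybrid Temporal Segmentation and Temporal-CNN Mapping of Forest
    Disturbances in Annual Landsat Time Series
Version: 0.1.0
Authors@R:
    person("Forest", "Dynamics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and classifies forest disturbances (insect defoliation
    by severity, wildfire, harvesting, windthrow, water extension) in annual
    six-band Landsat-style surface-reflectance time series. Combines a
    LandTrendr-style piecewise-linear temporal segmentation of the
    normalized burn ratio (NBR) with a one-dimensional temporal
    convolutional network (TempCNN) classifier over ten-year spectral
    subsequences. Includes a class-conditional synthetic trajectory and
    scene simulator, training-data construction rules (dNBR severity
    labelling, eligibility filters, composite rare-class signatures,
    spatial cross-validation), per-pixel annual map assembly with sieve and
    wetland post-processing, and design-based accuracy assessment
    (confusion matrices, omission/commission, stratified area-adjusted
    estimates, plot-level defoliated-biomass analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
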