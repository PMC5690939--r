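Package: contourvar
Title: Uncertainty Decomposition for Contour Propagation in Adaptive
    Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures interobserver, intraobserver, and total contour
    variation between radiotherapy structure sets with a directed mean
    surface-distance statistic, decomposes residual deformable-registration
    error in quadrature, synthesizes combined planning-margin expansions,
    and compares error sources with two-sample t-tests. Includes a seeded
    synthetic cohort generator that emulates two observers contouring
    organ phantoms on two CT studies with contour propagation through
    smooth B-spline displacement fields of known residual error.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
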