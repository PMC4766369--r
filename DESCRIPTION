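Package: edgewall
Title: Mechanics and Quantitative Imaging of Plant Cell Geometric Edges
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how local stiffness at the geometric edges of
    plant epidermal cells shapes cell geometry under turgor. Implements a 2D
    plane-strain finite-element model of a pressurized root-epidermis wall
    cross-section with vertex-localized softening, a sweep quantifying radial
    distension and vertex-to-face load relocation in maximum principal stress,
    a synthetic confocal-stack generator with membrane-proximal puncta and
    analytic ground truth, shell-based membrane-enrichment statistics with a
    two-way ANOVA stage, reciprocal SD-thresholded colocalization, and an
    exact test for 2x2 phenotype contingency tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
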