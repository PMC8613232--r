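Package: alphavessel
Title: Alpha-Shape Descriptors of Retinal Microvascular Morphology
Version: 0.1.0
Authors@R:
    person("Alphavessel", "Developers", email = "alphavessel@example.org",
           role = c("aut", "cre"))
Description: Quantifies the global morphology of retinal vessel skeletons with
    2D alpha-shapes built by circumradius filtering of a Delaunay
    triangulation.  Computes the optimal-alpha complexity descriptor, the
    optimal alpha-shape area (spread), their ratio (vessel shape, VS), and the
    robust-regression gradient of VS across a spur-erosion series.  Includes
    comparator fractal-dimension estimators (box counting and generalised
    sandbox), a seeded generator of synthetic vascular skeletons with
    neovascular-tuft and lesion-noise modes, group-comparison and bootstrapped
    regularised-logistic-regression feature-importance analyses, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    interp,
    glmnet,
    png,
    pixmap,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    deldir
Config/testthat/edition: 3
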