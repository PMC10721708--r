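Package: deformcyte
Title: Video-Based Deformability Cytometry Classification of Fetal and
    Adult Red Blood Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end analysis pipeline for classifying red blood cells
    as fetal or adult from high-speed video of flow through a microfluidic
    constriction.  Includes a synthetic video generator with planted ground
    truth, temporal-median background subtraction and blob detection,
    overlap-based multi-object tracking with fixed-size clip extraction, a
    two-pathway (slow/fast) spatiotemporal convolutional network classifier
    trained with stochastic gradient descent, donor-disjoint
    cross-validated evaluation with the usual classification metrics, a
    mixed-model donor-effect analysis with a boundary likelihood-ratio
    test for the fold variance component, and a data-ramping experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lme4,
    lmerTest,
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
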