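Package: kinsweep
Title: Marker-Set Sensitivity Analysis for Constrained Lower-Extremity
    Kinematic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how the placement and quantity of thigh and
    shank tracking markers affect lower-extremity joint kinematics computed
    with a constrained (joint-restricted) kinematic model. Provides a
    self-contained articulated lower-extremity model (ball hip, mobile-hinge
    knee with prescribed tibiofemoral translations, oblique universal ankle,
    hinge forefoot), model scaling from a static pose, fast per-frame
    constrained inverse kinematics, an unconstrained six degree-of-freedom
    comparator based on SVD rigid-body pose fits, a marker-dropout sweep
    over all 256 thigh/shank marker combinations, and the associated
    statistics layer (RMS error, cross-correlation, range of motion,
    subject-level bootstrap confidence bands, polynomial error-decay fits,
    5-degree equivalence testing, and walking-speed comparisons). A
    synthetic treadmill-gait generator with a calibrated soft-tissue
    artifact model makes the whole pipeline testable end-to-end without
    laboratory data; TRC marker files are read and written natively.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
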