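Package: levatorfem
Title: Finite-Element Simulation of Levator Ani Stress During Vaginal Delivery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quasi-static large-deformation finite-element simulation of the
    levator ani muscle (LAM) during the second stage of vaginal delivery.
    Provides an N-term Ogden hyperelastic material model with constrained
    nonlinear least-squares parameter identification from uniaxial
    stress-stretch data, parametric synthetic anatomy (fetal head, bony
    pelvis, labelled levator shell) generated from standard obstetric
    diameters, a cardinal-movements rigid-body trajectory for the fetal head
    (descent along the curve of Carus, internal rotation, extension),
    a quasi-static Newton solver with frictionless penalty contact against
    rigid surfaces, and per-region von Mises stress summaries, loading-order
    and elongation reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
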