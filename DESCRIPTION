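Package: fibrocrack
Title: Anisotropic Crack Phase-Field Modelling of Fibrous Soft Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-strain crack phase-field modelling of progressive damage and
    rupture in fibrous soft biological tissue. Implements the
    Holzapfel-Gasser-Ogden hyperelastic model with two collagen fibre families,
    quadratic energy degradation, an anisotropic crack surface density built on a
    fibre-aligned structure tensor, an energy-based anisotropic failure criterion
    with an irreversible history field, and a one-pass operator-splitting
    (staggered) finite element solver for the coupled deformation/phase-field
    problem. Includes closed-form homogeneous responses for uniaxial extension and
    in-plane simple shear, nonlinear least-squares identification of the elastic
    constants from stress-strain curves, a synthetic stress-strain data generator,
    programmatic generation of a single-edge-notched plate and of a multi-layer
    aortic tube segment with an initial tear, and canned studies for parameter
    fitting, crack-angle sensitivity to the anisotropy parameter, and an
    extension-inflation-torsion dissection demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    tibble,
    generics,
    rlang,
    ggplot2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr,
    xml2
Config/testthat/edition: 3
SystemRequirements: C++17
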