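Package: scespect
Title: Synthetic Compound-Eye Brain SPECT Design Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design-study toolkit for stationary brain SPECT systems built
    from hundreds of minifying micro-camera elements on a spherical
    support, each pairing a pixelated CZT detector having depth-of-
    interaction readout with a single narrow tungsten aperture (lofthole,
    micro-slit or micro-ring).  Provides helmet geometry construction,
    analytic ray tracing through parametric aperture solids with edge
    penetration, sparse system-response-matrix assembly, digital phantoms,
    ordered-subset expectation-maximisation reconstruction, Fisher-
    information images, aperture signal-to-noise analysis and standard
    image-quality metrics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
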