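Package: helicycle
Title: Mechano-Chemical Cycle Analysis of Helicase Unwinding Under Force
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic modelling and single-molecule trace analysis for DNA
    helicases probed in dual-trap optical tweezers. Implements the six
    candidate mechano-chemical cycles obtained by combining a Brownian-ratchet
    or power-stroke translocation mechanism with placement of the
    translocation step at ATP binding, hydrolysis, or product release;
    computes their steady-state velocities and force-dependent
    Michaelis-Menten parameters in an opposing-force geometry (Bell-type rate
    coupling) and a hairpin-under-tension geometry (fork-opening probability
    coupling); simulates passive-mode stepping traces by exact stochastic
    simulation with worm-like-chain tether mechanics; reproduces the standard
    trace-processing chain (bandwidth smoothing, contour conversion, windowed
    force-velocity estimation, binning); and selects among the six cycles by
    globally fitting binned velocity surfaces with multi-start least squares.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    lhs,
    minpack.lm,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
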