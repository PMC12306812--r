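Package: ohcamp
Title: Outer Hair Cell Cochlear-Amplifier Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Linearized model of the cochlear outer hair cell (OHC) as a
    local amplifier: a two-state piezoelectric membrane motor coupled to the
    cell's RC membrane circuit and to a forced damped mechanical oscillator,
    closed by hair-bundle mechanotransduction feedback. Provides the exact
    complex frequency response of the closed loop, high- and low-frequency
    closed-form approximations with their anti-damping and stiffness
    coefficients, gating compliance, an independent time-domain integration
    oracle, parameter derivations from morphological and electrical
    measurements, a guinea-pig 4 kHz reference scenario, seeded randomized
    scenarios for property testing, and sweep, figure and coefficient-report
    tooling.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    signal,
    ggplot2,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
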