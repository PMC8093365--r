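Package: twotone
Title: Two-Population Model of Auditory Streaming with Fast Excitation and
    Slow Delayed Inhibition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a periodically forced two-population
    Wilson-Cowan network with fast mutual excitation and slow delayed
    inhibition, a minimal cortical circuit for auditory streaming of
    alternating two-tone (ABAB) sequences. Provides a fourth-order
    method-of-steps integrator for the delay differential equations with
    Heaviside or sigmoid gain, threshold-crossing detection and percept
    labelling (integration, segregation, bistability, saturation), an
    event-driven simulator of the slow-fast singular limit with closed-form
    event times, the analytic classification of 2TR-periodic states via
    binary matrix forms with full existence conditions, fission and coherence
    boundary curves, and (presentation rate, frequency difference) parameter
    sweeps that assemble van Noorden diagrams.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
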