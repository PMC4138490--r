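Package: ubcsim
Title: Biophysical Simulation of Cerebellar Unipolar Brush Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-compartment conductance-based model of the cerebellar
    unipolar brush cell (UBC). Implements a 13-compartment morphology with
    ten ionic mechanisms (Hodgkin-Huxley gates, a 13-state Markov resurgent
    sodium scheme, GHK calcium permeation), sub-membrane calcium shell
    dynamics, and a generic second-messenger cascade that couples synaptic
    train stimulation to modulation of H- and TRP-channel gating, producing
    the late-onset response (LOR). Includes current- and voltage-clamp
    protocol runners, spike and passive-transient analysis (tri-exponential
    fits), conductance robustness sweeps, LOR response-space mapping, and a
    synthetic trace generator for testing the analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
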