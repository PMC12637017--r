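Package: thickEM
Title: Image Contrast Simulation for Thick Vitrified Specimens in TEM and STEM
Version: 0.1.0
Authors@R:
    person("E.", "Mills", email = "emills@example.org", role = c("aut", "cre"))
Description: Simulation of phase and amplitude contrast in electron microscopy
    of thick (100 nm to 1 um) vitrified biological specimens.  Provides a
    parametric constructive-solid-geometry model of a T4-like bacteriophage
    embedded in vitreous ice, a multislice engine for bright-field TEM phase
    contrast with coherence envelopes and energy-loss dose budgeting,
    tilt-corrected bright-field (tcBF) 4D-STEM by reciprocity with parallax
    correction on segmented annular detectors, a low-loss EELS model with
    log-ratio thickness estimation, and a lightweight Monte Carlo simulator of
    incoherent (amplitude) STEM contrast from elastic and inelastic electron
    scattering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
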