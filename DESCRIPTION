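Package: ectspec
Title: Analysis of Electrochemical Tunneling Spectroscopy Current-Distance Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for electrochemical scanning tunneling spectroscopy (ECTS)
    current-distance (I-z) curve ensembles: a plain-text curve format with
    metadata headers, per-curve exponential distance-decay-factor (beta)
    estimation with faradaic-leakage handling, local tunneling barrier height
    profiles via the square-barrier relation with spatial-periodicity
    detection, electrochemical-gating series analysis (resonance minimum,
    on/off ratio, absolute energy scale), a forward model simulating realistic
    I-z acquisitions (set point, amplifier saturation, leakage floor,
    multiplicative and additive noise, curve-to-curve beta dispersion,
    oscillatory barriers, gate-dependent beta), and diffuse-double-layer
    electrostatics (Debye length, analytic Gouy-Chapman decay, a nonlinear 1-D
    Poisson-Boltzmann solver for a confined electrolyte gap).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
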