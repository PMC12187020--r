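Package: dyadPNP
Title: Nano-Scale Electrodiffusion in the Cardiomyocyte Dyad
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-volume simulator of electrodiffusion in the cardiomyocyte
    dyad based on the Poisson-Nernst-Planck (PNP) equations with stationary
    calcium binding buffers.  Ion channels (K+, Na+, Ca2+) and the
    sodium-calcium exchanger (NCX) are represented as internal flux boundary
    conditions on an adaptive tensor-product mesh, advanced with a first-order
    operator splitting: an explicit buffering step followed by a fully coupled
    implicit Poisson/Nernst-Planck step.  The package ships the reduced models
    commonly used for the dyad (pure diffusion, reaction-diffusion with an
    imported membrane potential, and one- and two-compartment ODE models),
    diagnostics (Debye layer profiles, charge density, per-term magnitudes of
    the transport equation, ryanodine receptor activation time), scenario
    presets, VTK rectilinear output, and a command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
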