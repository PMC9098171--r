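Package: setsolv
Title: Ion-Surfactant Parameterization for Dissipative Particle Dynamics
    via Setschenow Coefficients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to parameterize ion-surfactant interactions in
    dissipative particle dynamics (DPD) by matching salting-out behaviour.
    Provides a DPD simulation engine for nonionic surfactants with added
    salt (soft Groot-Warren repulsions, harmonic bonds and angles, pairwise
    dissipative/random thermostat, Slater-smeared Ewald electrostatics,
    NVT/NPT), micelle identification and critical micelle concentration
    (CMC) extraction from aggregation-number distributions, conversions
    between reduced DPD and physical units, and a separable model linking
    Setschenow coefficients to ion-tail repulsion amplitudes, with fitting
    routines for surfactant constants and ion parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
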