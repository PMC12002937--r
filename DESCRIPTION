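Package: osteomg
Title: Coupled Kinetics of Biodegradable Magnesium Implant Corrosion and
    Peri-Implant Bone Mineralization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ordinary-differential-equation models of peri-implant bone
    growth and mineralization coupled to the corrosion kinetics of
    biodegradable magnesium-gadolinium implants. Implements two implant
    volume-loss laws (diffusion-limited power law and surface-rate law with
    precipitation), an extended Komarova-type bone mineralization system
    with a generalized-inhibitor coupling to Mg ion release, and
    hydroxyapatite ultrastructure dynamics (crystal-width growth and
    lattice-spacing substitution/recovery). Provides closed-form oracles
    for the degradation, crystal-width and lattice equations, a staged
    CMA-ES calibration workflow with latin-hypercube multi-start, residual
    error metrics with margin-of-error confidence bands, variance-based
    Sobol sensitivity analysis via Saltelli sampling, and a synthetic-study
    generator emulating sparse animal-study designs for parameter-recovery
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    lhs,
    pracma,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
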