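Package: phypif
Title: Kinetic Modeling of Light-Driven Phytochrome-PIF Interaction Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reaction-kinetic modeling and estimation for the light-regulated
    interaction between plant phytochrome B and phytochrome-interacting
    factors (PIFs). Implements the five-species reaction network coupling
    red/far-red-driven Pr-Pfr photoconversion to reversible PIF binding,
    its numerical integration under arbitrary piecewise-constant
    illumination protocols, a closed-form photostationary solution with
    dose-response scan utilities, a suite of estimators for time-resolved
    fluorescence, absorbance, titration, Arrhenius, circular-dichroism
    melting, and fluorescence-correlation-spectroscopy data, hydrodynamic
    calculations (Stokes-Einstein, Smoluchowski encounter rates), and
    seeded synthetic-data generators so that every estimator can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
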