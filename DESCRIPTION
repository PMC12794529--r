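Package: txasim
Title: Model-Based Tranexamic Acid Dose Simulation for Pediatric Trauma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates tranexamic acid (TXA) plasma exposure in virtual
    adult and pediatric trauma populations from a published two-compartment
    population pharmacokinetic model with platelet count, tissue oxygen
    saturation (NIRS) and interleukin-8 covariate effects on clearance.
    Provides allometric pediatric scaling, seeded virtual-population
    generation from covariate ranges, closed-form simulation of intravenous
    infusion regimens with proportional residual error, noncompartmental
    exposure metrics (Cmax, AUC over 0-4 h and 0-8 h, time above a
    concentration threshold), and dose-comparison reports supporting
    exposure-matched bolus dose selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
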