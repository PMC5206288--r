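Package: alchlogd
Title: Post-Processing of Alchemical Free-Energy Calculations for
    Distribution-Coefficient Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Free-energy estimation from alchemical sampling (Zwanzig
    exponential averaging and the multistate Bennett acceptance ratio),
    cutoff and finite-size correction terms for Barker-Watts reaction-field
    simulations (intramolecular functional-form, Lennard-Jones long-range,
    summation-scheme and polarization pass-through corrections), assembly of
    solvation free energies under four correction models, water/cyclohexane
    distribution-coefficient prediction under dominant-species and
    two-species approximations with effective pKa speciation, and bootstrap
    benchmark statistics (MUE, R squared, MUD with percentile confidence
    intervals). Includes synthetic-data generators with analytic ground
    truth so every stage is testable without molecular-dynamics output, and
    a packaged reference table of solvation free energies for a small-
    molecule benchmark set.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
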