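Package: bbbms
Title: Quantitative Systems Pharmacology Simulator of Blood-Brain Barrier
    Integrity and Relapse Dynamics in Relapsing-Remitting Multiple Sclerosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulator coupling blood-brain barrier (BBB) integrity
    (tight-junction protein level, endothelial density, TEER and permeability
    readouts) to a stochastic immune and relapse layer for relapsing-remitting
    multiple sclerosis. Includes one-compartment pharmacokinetics for the
    SCO-spondin-derived peptide NX210 and its cyclic form NX210c, sigmoidal
    Emax pharmacodynamic coupling onto barrier repair, effect handles for five
    standard-of-care treatments, seedable heterogeneous virtual-patient
    populations, and an in silico trial engine with paired-arm designs, relapse
    detection and endpoint aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
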