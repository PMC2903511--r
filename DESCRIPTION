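Package: pbtkmix
Title: Generalized Multi-Chemical Physiologically Based Toxicokinetic Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A generalized, physiologically consistent toxicokinetic (PBTK)
    simulation engine for chemical mixtures. Structurally diverse
    chemical-specific models -- biokinetic networks for toxic metals
    (cadmium, lead, chromium, methylmercury, arsenic and its methylated
    metabolites) and perfusion-limited inhalation models for volatile
    organics (benzene, toluene) -- are mapped onto one chemical-independent
    whole-body compartment network and integrated simultaneously as a
    matrix system of stiff ordinary differential equations. Supports
    first-order reaction networks, Michaelis-Menten metabolism with
    competitive and noncompetitive inhibition and enzyme induction,
    multi-route exposure (oral bolus, continuous dietary, inhalation),
    cross-chemical metabolic interactions with lagged exposure-response
    modulation of maximum reaction velocities, mass-conservation ledgers,
    population variability sampling, and scenario files with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    Matrix,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
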