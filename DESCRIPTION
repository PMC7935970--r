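Package: ccswitch
Title: Phosphorylation-Operated Coiled-Coil Switches: Design, Kinetics and
    Membrane-Targeting Quantitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing phosphorylation- and
    dephosphorylation-operated coiled-coil (CC) heterodimer switches and their
    coupling to reversible lipid-membrane targeting. Provides heptad-register
    bookkeeping, kinase-motif placement and helical-wheel/hydrophobic-moment
    analysis for switch peptides; average and monoisotopic mass and extinction
    coefficient calculators; an a-a' pairing-energy ranking and a two-state
    bimolecular thermal-denaturation model; a dissociation-gated
    phosphorylation kinetic model (ODE) with membrane-tether and
    avidity-switch extensions; exponential, constant and melting-midpoint
    fitting procedures with an unpaired t test; confocal z-stack quantitation
    (z-profiles, peak intensity time courses, baseline-subtracted peak areas);
    and seeded synthetic-data generators (HPLC peak areas, CD traces and
    melts, supported-lipid-bilayer z-stack series) for end-to-end parameter
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    deSolve,
    minpack.lm,
    signal,
    stats,
    utils,
    tiff,
    withr,
    yaml
Suggests:
    pracma,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
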