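Package: micellr
Title: Micellization and Cyclodextrin Complexation Analysis from
    Fluorescence Titrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines critical micelle concentrations (CMC) from
    fluorescence titrations by two-segment least-squares breakpoint
    regression, builds micellar diagrams (apparent CMC versus cyclodextrin
    concentration), fits 1:1 and sequential 1:2 host-guest complexation
    models to extract association constants with bootstrap uncertainty and
    nested-model stoichiometry selection, and computes ligand-efficiency
    metrics (binding energy per heavy atom). Includes a synthetic-data
    generator with known ground truth for end-to-end validation of the
    inference chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
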