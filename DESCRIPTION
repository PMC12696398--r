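Package: mediaforge
Title: Custom Cell-Culture Media Formulation and Bench Stoichiometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A scriptable toolkit for designing and preparing custom
    cell-culture media (the DMEM family ships built in): a compound registry
    with stock multipliers and solvents, stock and master-stock planning with
    automatic water back-fill, preset media for Seahorse respirometry,
    nutrient-depletion, SILAC labeling and stable-isotope tracing experiments,
    isotope-aware monoisotopic mass and protonated m/z computation for labeled
    tracers, and the derived assay summaries used alongside such media:
    sulforhodamine-B doubling analysis and Seahorse mito-stress metrics, with
    seeded simulators so every stage is testable without instruments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
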