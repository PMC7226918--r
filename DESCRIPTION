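Package: cultscreen
Title: Analysis of Culturable Plant-Microbiota Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational layer of a culturable plant-microbiota
    screen: dereplication of bacterial isolates into RAPD haplotypes by
    band-profile identity, richness and Venn-partition analysis of taxa shared
    across plant compartments (flower, leaf, stem, bulk soil), censored
    minimum-inhibitory-concentration (MIC) calling from ordinal growth grades
    over antibiotic concentration ladders, cross-streak antagonism scoring
    (per-tester total score of inhibition and compartment-level
    inhibitory/sensitivity aggregation), essential-oil chemotype
    summarization with linear retention index arithmetic, and seeded
    synthetic-data generators that emulate the study design so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
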