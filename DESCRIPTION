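Package: gdqsr
Title: Operationalized Global Diet Quality Score Collection and Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for collecting and scoring the Global Diet Quality Score
    (GDQS) with the cube-based, operationalized quantity cutoffs. Implements
    the food-group taxonomy with the published cube set, gram cutoffs and
    mean food-group densities; a master food database with fuzzy search and
    probe-descriptor classification; a seven-step 24-hour open-recall
    interview state machine with mixed-dish decomposition; conversion of
    cube selections into quantity categories and gram estimates, including
    the high-fat-dairy milk-equivalent merge; the liquid-oils inference
    algorithm; configurable point-table scoring with submetrics; and the
    density-derivation pipeline (percentage gram contributions, top-5
    ranking, mean-rank aggregation, gram-to-volume conversion and 1-D cube
    clustering). Seeded synthetic-data generators provide all fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
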