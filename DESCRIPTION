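Package: nichepop
Title: Niche Analysis, Demography, and Red-List Assessment for Small
    Plant Populations
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantitative tools for conservation assessments of narrowly
    distributed plants from quadrat-survey, census, and soil data.
    Computes species importance values (relative abundance, height, and
    cover), Levins and Shannon niche breadth, and Pianka niche overlap
    matrices from plot surveys; summarises stage-structured census tables
    and flags continuing population decline; encodes IUCN Red List
    criteria C and D and a screen for Plant Species with Extremely Small
    Populations (PSESP); and fits a redundancy analysis (RDA) of plant
    growth and flowering traits on soil physicochemical variables from
    first principles, with forward selection, pseudo-F statistics, and
    permutation p-values.  Seeded simulators generate community, census,
    and soil-trait tables with the statistical structure the analyses
    assume, so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
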