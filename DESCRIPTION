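Package: skyisland
Title: Climate-Envelope Habitat Modelling for Alpine 'Sky Island' Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for presence/pseudo-absence species
    distribution modelling of alpine specialists on mountainous terrain:
    terrain predictors from a digital elevation model (transformed aspect,
    slope, compound topographic index via D8 flow accumulation, vector
    ruggedness), occurrence-record filtering, constrained pseudo-absence
    backgrounds, a bootstrap-aggregated tree-ensemble classifier with a
    sensitivity-constrained suitability threshold, projection across a
    factorial grid of climate-change scenarios, and patch-based habitat
    configuration metrics (range change, patch number, size and elevation).
    A seeded synthetic-landscape generator supplies inputs with the
    statistical structure the analysis assumes, so the whole pipeline is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
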