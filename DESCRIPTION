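Package: wannmwr
Title: Weight-Agnostic Neural Architecture Search for Microwave Radiometry Breast-Cancer Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-phase neural architecture search for classifying breast-cancer
    risk from medical microwave radiometry (MWR) temperature profiles. Phase one
    evolves sparse feedforward network topologies weight-agnostically (shared-weight
    evaluation, NEAT-style structural mutations, three-objective NSGA-II ranking,
    tournament selection); phase two optimizes the fixed topology's connection
    weights with BIPOP-CMA-ES (doubling-population restarts) against cross-entropy.
    Includes a cascade-correlation network baseline, a synthetic generator for
    bilateral MWR-like temperature data, stratified class balancing and splitting,
    and evaluation and model-comparison metrics for imbalanced binary classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
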