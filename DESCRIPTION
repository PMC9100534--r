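Package: nichecast
Title: Climate Niche Models with Maximum Entropy and Scenario Projection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Presence-background climate niche modelling for invasive species
    risk assessment. Implements an L1-regularized maximum-entropy (Gibbs
    distribution) niche model with bootstrap ensembling, spatial thinning of
    occurrence records by overlapping buffers, Spearman-correlation variable
    pruning, habitat suitability classification with climate-unit overlap
    summaries, multivariate environmental similarity surfaces (MESS) for
    extrapolation detection, and identity-line regression tests of
    distribution change under climate scenarios. Includes a synthetic-world
    generator with known suitability truth so the whole pipeline is testable
    end to end, plus single-band GeoTIFF and ESRI ASCII grid I/O.
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
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    geosphere,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
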