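Package: ratefa
Title: Psychometric Pipeline for Multi-Rater Animal Personality Ratings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for trait-rating studies in which
    several observers score the same animals on adjective items in one or
    more situations. Provides inter-rater reliability screening with
    two-way consistency intraclass correlations, minimum-residual
    exploratory factor analysis with oblimin rotation and a three-way
    factor-count vote (parallel analysis, empirical BIC, very simple
    structure), sampling-adequacy and communality item screens,
    cross-group structural comparison via orthogonal Procrustes rotation
    and Tucker's congruence, fuzzy-set intersections of factor loadings
    with a permutation salience threshold, ten Berge correlation-preserving
    factor scores, and a seeded synthetic-data generator with known latent
    structure for validation. Ships the published macaque loading matrices
    used by the worked examples.
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
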