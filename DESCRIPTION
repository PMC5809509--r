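Package: elevdisp
Title: Phylogenetic and Functional Dispersion of Assemblages Along
    Elevational Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Abundance-weighted community phylogenetics for multi-transect
    elevational surveys of woody-plant assemblages. Computes the net
    relatedness index (NRI) and the standardized effect size of the
    between-assemblage mean pairwise distance (S.E.S. D_pw) under a
    tip-shuffle null model, decomposes dispersion into alpha, beta and
    gamma components over elevational bands, builds functional-trait
    dendrograms (log-standardize, PCA, UPGMA), quantifies phylogenetic
    signal (Blomberg's K, Pagel's lambda), and fits the gradient-statistics
    layer: linear/quadratic OLS with AIC choice, simple OLS screens,
    forward stepwise regression, Mantel tests, multiple regression on
    distance matrices, and three-set variation partitioning. A synthetic
    data generator produces phylogenies, lambda-scaled Brownian traits,
    monotone climate gradients and communities assembled under neutral,
    environmental-filtering or limiting-similarity rules, so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    phytools,
    picante,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
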