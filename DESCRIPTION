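Package: ionosig
Title: Ionomic Signatures of Single-Nutrient Deficiency from Multi-Element
    Plant Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of plant functional-ionome profiles under single-nutrient
    deprivation. Provides derived nutrient metrics (elemental quantity, net
    uptake over all subtractive replicate combinations, relative root nutrient
    content, delta-delta-Ct relative expression, masked and clipped relative
    heatmaps), nonparametric rank tests (Kruskal-Wallis, exact and approximate
    Wilcoxon rank-sum, Dunn post hoc, compact letter displays), a partial least
    squares discriminant analysis (PLS-DA) engine built on NIPALS with
    Mahalanobis-distance class prediction, cross-validated selection of latent
    components and variable importance in projection (VIP), a repeated
    stratified-split evaluation protocol with four truncated-prediction
    variants, VIP-based ionomic signature extraction with hierarchical
    clustering on principal components, and a seeded synthetic ionome
    generator that emulates a two-species, multi-tissue deprivation trial.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
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
    mixOmics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
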