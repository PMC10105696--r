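Package: molargm
Title: Landmark and Semilandmark Geometric Morphometrics for Tooth Outlines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete 2D geometric-morphometrics toolkit for occlusal tooth
    outlines digitised as fixed landmarks plus sliding semilandmarks, built
    for morphometric zooarchaeology. Reads tpsDig-dialect TPS files and
    specimen metadata, performs Generalized Procrustes Analysis with
    bending-energy sliding of semilandmarks, tangent-space principal
    component analysis, permutation-based Procrustes ANOVA, size tests with
    Benjamini-Hochberg correction, allometry regression, canonical variate
    analysis with leave-one-out cross-validated classification, linear
    discriminant assignment of archaeological unknowns, and neighbour-joining
    phenograms from Mahalanobis distances. Ships a synthetic-data generator
    that emulates the group structure of a two-subspecies, wear-stratified
    molar study so the full pipeline can be exercised and validated without
    access to specimen data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    yaml
Suggests:
    ape,
    MASS,
    phangorn,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
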