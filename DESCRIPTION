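Package: milkphylo
Title: Multivariate Phylogenetic Analysis of Milk Macronutrient Composition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of mammalian milk macronutrient
    composition (fat, protein, sugar) on a phylogeny. Implements logit-scale
    quality control and transforms, a trivariate phylogenetic mixed model with
    ecological fixed effects and phylogenetic/residual covariance estimation
    (maximum likelihood and MCMC backends), univariate and exact multivariate
    Kolmogorov-Smirnov Importance tests for clade distinctiveness, scalar
    Ornstein-Uhlenbeck shift-regime detection with optima estimation and
    missing-data imputation, phylomorphospace and nutritional-geometry plots,
    a seed-deterministic synthetic-data generator, and a pipeline orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    phytools,
    glmnet,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
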