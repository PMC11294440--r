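Package: ancniche
Title: Climatic Niche Evolution from Occurrence Records, Ensemble Niche
    Models, and Dated Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for studying climatic niche evolution in
    a clade: spatial thinning of occurrence records, pseudo-absence
    sampling, correlation-based pruning of bioclimatic predictors,
    ensemble species distribution modelling (GLM, GAM, boosted trees and
    an L1-regularised MaxEnt-style surrogate) evaluated with AUC, Cohen's
    kappa and the true skill statistic, predicted niche occupancy (PNO)
    profiles with Schoener's D and Hellinger-based I overlap statistics,
    and maximum-likelihood ancestral reconstruction of climatic
    tolerances under Brownian motion on a dated ultrametric phylogeny.
    Includes a synthetic-data generator (smooth climate surfaces,
    Gaussian-niche species, pure-birth chronograms, Brownian traits) so
    every stage is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    glmnet,
    jsonlite,
    mgcv,
    splines,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    geosphere,
    phytools,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
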