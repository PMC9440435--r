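Package: phenogrowth
Title: High-Throughput Phenotyping Analysis of Wheat Growth Under Heat and Drought
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for high-throughput greenhouse phenotyping of
    wheat under combined high temperature and water deficit: trait quality
    control (Grubbs outlier screening, imputation, replicate-reproducibility
    filtering, stepwise VIF collinearity removal), per-day partitioning of
    phenotypic variance into genotype, environment and interaction effects
    expressed as LOD scores, gravimetric evapotranspiration with soil-only
    correction, cross-validated prediction of aboveground biomass from
    image-derived geometry, bell-shaped growth-curve modelling with Timemax
    extraction, and drought/heat stress-tolerance indices. Includes a
    synthetic "virtual greenhouse" generator that emulates the experimental
    design and provides ground truth for every downstream step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    glmnet,
    e1071,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
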