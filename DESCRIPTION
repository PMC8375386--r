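Package: geotrace
Title: Microbial Source Geolocation from City OTU Count Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A pipeline for predicting the city of origin of environmental
    microbiome samples from OTU count tables at the order, family and species
    ranks. Implements depth and ubiquity pre-filters, voom-style log2
    counts-per-million normalization, one-vs-rest elastic-net retention
    counting for city-discriminative taxon selection, a repeated-split voting
    protocol over random forest, RBF support vector machine and multilayer
    perceptron back-ends with top-1 and top-2 vote error, mystery-class
    augmentation for flagging samples from unseen cities, k-means
    discretization of city climate covariates into ordinal traits, and a
    multi-output neural network that predicts six categorical city traits to
    narrow candidate origins. A synthetic-data generator reproduces the
    statistical structure the analysis assumes (city signatures, multi-year
    batch shifts, depth outliers, climate profiles) for testing and
    calibration.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
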