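Package: suitscape
Title: Environmental Suitability Modelling for Mosquito Occurrence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Species distribution modelling workflow for trap-based mosquito
    surveys: temporal Fourier summarisation of monthly environmental raster
    time series into seasonality components, presence/absence preprocessing
    with per-cell deduplication and pseudo-absence generation in unsuitable
    land cover, and three balanced-ensemble suitability models (clustered
    non-linear discriminant analysis, balanced-subset random forests, and
    bootstrapped logistic regression), each mapping environmental covariates
    to a suitability score in [0,1]. Includes a synthetic landscape and
    survey generator with known truth for end-to-end validation, evaluation
    by sensitivity and specificity with stratified bootstrap confidence
    intervals, Moran's I correlograms, and a configuration-driven pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    ranger,
    glmnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
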