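Package: commstack
Title: Two-Step Sequential Ensemble Prediction of Plant Community Abundances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting fine-scale species abundances in annual
    plant communities from easy-to-measure abiotic variables. Implements a
    sequential stacked ("two-step") ensemble in which a first model predicts
    every species' abundance from soil chemistry and annual precipitation
    alone, and a second model predicts each focal species' abundance from the
    abiotic variables plus the predicted abundances of its competitors, so
    that deployment never requires observed abundances. Includes Spearman
    correlation-cluster feature filtering with a random-noise permutation
    importance benchmark, spatial block cross-validation, repeated random
    split and leave-one-year-out evaluation, Moran's I diagnostics, a
    calibrated zero-inflated synthetic community generator with stored ground
    truth, and a minimal covariate-modulated Beverton-Holt annual plant
    competition model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ranger,
    readr,
    stats,
    tibble,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
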