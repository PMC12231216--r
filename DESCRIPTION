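Package: stingrisk
Title: Ensemble Ecological Niche Models and Envenomation Vulnerability Maps
Version: 0.1.0
Authors@R:
    person(given = "Package", family = "Author", role = c("aut", "cre"),
           email = "author@example.org")
Description: Tools for mapping envenomation risk from presence-only species
    records: spatial thinning of occurrences, ecoregion-constrained
    pseudo-absence sampling with prevalence weighting, variance-inflation-factor
    predictor screening, an ensemble of five presence/background classifiers
    (weighted GLM, GAM, boosted trees, random forest, and a penalized-logistic
    Maxent), repeated split-sample evaluation with AUC and the true skill
    statistic, sensitivity-specificity sum maximization binarization, and
    vulnerability maps defined as exposure times distance to the nearest
    healthcare-providing city. A virtual-species simulator with known response
    surfaces supports validation of the whole pipeline at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    mgcv,
    ranger,
    xgboost,
    glmnet,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    pROC
Config/testthat/edition: 3
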