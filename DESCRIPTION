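Package: bipolaRF
Title: Predictive Modelling of Bipolar Radiofrequency Ablation Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modelling the efficacy (lesion transmurality) and
    safety (steam-pop occurrence) endpoints of bipolar catheter-to-catheter
    radiofrequency ablation. Provides a seeded synthetic-cohort generator
    emulating an ex vivo ablation experiment, a binomial logit-link GLM
    fitter with honest convergence and separation diagnostics, exhaustive
    predictor-subset model search scored by validation AUC with DeLong
    variance and paired tests, Shapley-value attribution of validation AUC
    to predictors, the two-predictor steam-pop risk-boundary isopleth in the
    thickness-by-power plane, and inversion of a fitted transmurality model
    to predicted lesion depth and required ablation duration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
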