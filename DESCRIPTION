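Package: periopolicy
Title: Longitudinal Modified Treatment Policies for Periodontal Care and
    Tooth Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how hypothetical policies that restrict or
    expand the yearly receipt of subsidised periodontal therapy would change
    the ten-year cumulative incidence of first non-surgical tooth extraction.
    Provides a seeded synthetic registry-cohort generator with time-varying
    confounding, treatment-confounder feedback and informative censoring;
    three policy scenarios (no care in consecutive years, no supragingival
    care in consecutive years, stochastic extension of care into untreated
    years) as explicit treatment-history transformations; super-learner
    nuisance estimation; and sequentially doubly robust, g-computation and
    inverse-probability-weighted estimators of counterfactual cumulative
    incidence with censoring adjustment, cross-fitting and influence-function
    based inference, plus risk-difference and risk-ratio contrasts and exact
    ground-truth oracles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    pracma,
    ranger,
    rlang,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
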