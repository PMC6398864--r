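Package: textps
Title: Propensity-Score Models from Free-Text Clinical Notes
Version: 0.1.0
Authors@R: person("IPCI", "Methods Lab", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds propensity-score models for pharmacoepidemiological
    new-user cohort studies from unstructured electronic health record text.
    Provides a synthetic EHR generator with known channeling and
    confounding-by-indication structure, new-user NSAID episode construction
    with washout and switching rules, bag-of-words featurization of clinical
    notes, frequency and chi-square covariate selection, L1-penalized
    logistic propensity regression with cross-validated AUC, greedy
    one-to-many caliper matching, and Cox proportional-hazards estimation of
    hazard ratios under a grid of matching and adjustment designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    data.table,
    glmnet,
    survival,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
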