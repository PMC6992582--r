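Package: euploidcalc
Title: Per-Oocyte Euploidy Prediction and Minimum MII Oocyte Estimation for IVF/PGT-A
Version: 0.1.0
Authors@R:
    person("ART", "Modelling Group", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for predicting the probability that a metaphase-II (MII)
    oocyte develops into a euploid blastocyst in IVF/ICSI cycles with
    preimplantation genetic testing for aneuploidy (PGT-A), and for estimating
    the minimum number of MII oocytes (MIImin) needed to obtain at least one
    euploid blastocyst at a user-chosen success probability. Ships the published
    multicenter validation-model coefficient set (logistic model of female age,
    sperm source and study center), a synthetic case-report-form cohort
    generator with negative-binomial oocyte counts and hierarchical binomial
    thinning, the full model-fitting pipeline (count-distribution
    identification, adaptive-lasso covariate selection with AICc stopping,
    aggregated binomial logistic estimation), and validation machinery
    (holdout splits, oocyte-level ROC/AUC, generalized R-squared, model
    comparison, positive-predictive-value tables, Tukey-Kramer sensitivity
    analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    glmnet,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
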