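Package: cfrs
Title: Cell-Free DNA Copy-Number Response Score and ctDNA VAF Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds and evaluates a copy-number-based chemotherapy response
    score (RS) from gene-level cell-free DNA log2 copy ratios: a seven-criterion
    consensus feature filter (deviation, mutual information, AUC, chi-square,
    Wilcoxon, ANOVA, t-test), L1-penalized logistic scoring with accuracy-driven
    cross-validation, accuracy-optimal score dichotomization, and downstream
    outcome statistics (ROC/AUC, response-rate contingency tests, Kaplan-Meier,
    log-rank, Cox hazard ratios, quantile biomarker screens). A companion
    monitoring arm summarizes circulating tumor DNA variant allele frequencies
    at baseline and cycle 2, tests paired VAF dynamics within response groups,
    and associates cycle-2 detectability with response and progression-free
    survival. A seeded synthetic cohort generator with the statistical structure
    the analysis assumes makes the full pipeline testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    survival,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
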