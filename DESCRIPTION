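Package: recurisk
Title: Subgroup-Dissecting Prognostic Gene Signatures for Recurrence-Free
    Survival
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns two nearest-centroid gene-expression signatures from bulk
    tumor expression and recurrence-free-survival data, calls each tumor
    low-risk or one of two high-risk subgroups, and characterizes the
    subgroups. Training partitions recurrence tumors into candidate
    subgroups, prescreens genes by univariate Cox proportional hazards
    regression, and stabilizes the gene lists by rank-frequency selection
    over repeated cross-validation. Ships first-principles survival
    statistics (product-limit curves with Greenwood variance, two-group
    log-rank test, Cox partial-likelihood fits with Efron tie handling,
    concordance AUC), single-sample gene-set scoring, Wilcoxon group
    read-outs, a planted-subgroup synthetic cohort simulator, and a
    command-line workflow.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
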