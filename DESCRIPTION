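Package: pairsig
Title: Rank-Based Immune lncRNA Pair Signatures for Survival Prognosis
Version: 0.1.0
Authors@R:
    person("pairsig", "developers", email = "pairsig@example.org",
           role = c("aut", "cre"))
Description: Builds and evaluates prognostic signatures from binary
    expression-rank indicators of immune-related long noncoding RNA
    (lncRNA) pairs in tumor cohorts. Provides immune co-expression and
    differential-expression screening, construction of the 0/1 pair
    matrix with a low-information-pair filter, first-principles Cox
    proportional-hazards fitting (Efron and Breslow ties), Kaplan-Meier
    and log-rank statistics, repeated cross-validated LASSO-Cox feature
    selection by occurrence frequency, risk scoring, time-dependent ROC
    with Youden-index cutoff selection, independence and association
    analyses, single-sample gene-set enrichment (stromal/immune/ESTIMATE
    style scores), and a synthetic survival-cohort generator with
    planted prognostic pairs for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
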