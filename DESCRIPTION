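Package: divorph
Title: Classifying Orphan Proteins That Diverged Beyond Recognition
Version: 0.1.0
Authors@R:
    person("divorph", "maintainers", email = "divorph@example.org",
           role = c("aut", "cre"))
Description: Simulation-driven detection of orphan proteins that arose by
    sequence divergence beyond the reach of similarity searches. Simulates
    protein evolution under the LG substitution model with gamma rate
    heterogeneity, invariant sites and indels along a phylogeny; performs
    desk-scale Smith-Waterman searches with Karlin-Altschul E-values
    emitting standard 12-column tabular output; identifies eligible orphans
    from the non-significant hit band; extracts eleven hit-band statistics;
    and trains explainable classifiers (naive Bayes, logistic regression,
    random forest, gradient boosting) that separate diverged orphans from
    reversed-sequence negative controls, combined by majority-vote ensemble.
    Includes enrichment and group-comparison statistics for downstream
    analysis of divergence calls.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    glmnet,
    jsonlite,
    matrixStats,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
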