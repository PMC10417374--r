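Package: ipqtl
Title: Intermediate-Phenotype QTL Mapping and Genetic Risk Scores for
    Anthracycline Cardiotoxicity
Version: 0.1.0
Authors@R:
    person("ipqtl", "developers", email = "ipqtl@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting the genetics of cardiotoxicity due to
    anthracyclines (CDA) with intermediate molecular phenotypes (IMPs).
    Implements backcross interval mapping from scratch: hidden-Markov-model
    conditional genotype probabilities on a pseudomarker grid, EM and
    Haley-Knott genome scans, LOD-based peak classification, multi-QTL
    fixed models with percent-variance decomposition and drop-one-term
    testing, and comparison of basal cdaQTL models against models extended
    with ipQTLs. Includes IMP/pathophenotype association utilities
    (2^-ddCt quantification, normality-gated correlation and group tests,
    multiple-regression IMP selection, PCA median-split views), a
    candidate-SNV association layer for patient cohorts (five genetic
    models, imputation-quality filtering, LVEF-drop case labelling) with a
    bootstrap-LASSO polygenic risk score and Youden-index cutoff, plus a
    fully seeded synthetic-data generator (mediated-pleiotropy backcross
    cohorts and Hardy-Weinberg human cohorts) and end-to-end pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
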