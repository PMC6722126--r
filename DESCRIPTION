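Package: coresig
Title: Cohort-Specific Gene Signatures from a Curated Disease Gene Pool
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds cohort-specific case/control classifiers of brain gene
    expression from a curated pool of disease-associated genes. Genes are
    ranked within each cohort either by a sparse representation-based
    variable selection (SRVS) score, accumulated from l1-penalised
    regressions of the class label on random gene subsets, or by one-way
    ANOVA p-value. Top-n gene vectors are evaluated by Euclidean
    nearest-centroid classification under leave-one-out cross-validation,
    the best vector is selected by maximum classification ratio, and its
    significance is assessed by permutation over random gene sets of the
    same size. Classifier gene sets are compared across cohorts by Jaccard
    similarity, factor ANOVA on similarity, and cross-study summary
    statistics. Includes a synthetic-cohort generator with planted effects
    so the whole pipeline is testable without external downloads, plus
    readers for expression TSV, GEO Series Matrix text files, and gene-pool
    lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    knitr
Config/testthat/edition: 3
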