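Package: longisal
Title: Longitudinal Salivary Microbiome Analysis with Locally Sparse
    Varying Coefficient Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for longitudinal 16S salivary microbiome
    studies with repeated sampling of mice (or other subjects) across a
    fixed week grid.  Provides compositional preprocessing (half-minimum
    zero replacement, centered log-ratio transform, prevalence filtering,
    rarefaction, taxonomy aggregation), community ecology statistics
    (Yue-Clayton theta dissimilarity, permutation AMOVA, diversity
    indices), a locally sparse varying coefficient mixed model (LSVCMM)
    for per-taxon differential abundance over time with EBIC penalty
    selection and cluster-bootstrap simultaneous confidence bands,
    trajectory functional PCA with missing visits and per-genotype Lasso
    logistic prediction of diagnosis, zero-inflated copula
    conditional-dependence networks with StARS stability selection, and a
    seed-reproducible synthetic cohort generator with ground-truth effect
    annotations for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    glmnet,
    mvtnorm,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
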