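Package: netos
Title: Network-Based Target Overlap Scoring for Drug Combinations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes drug combinations by the overlap of their network
    perturbation neighborhoods. Drug target sets are propagated over a weighted
    protein-protein interaction network with a regularized Laplacian exponential
    diffusion kernel; significantly perturbed nodes are identified by Monte-Carlo
    permutation of target sets; the Target Overlap Score (TOS) is the Jaccard
    coefficient of two (or more) such neighborhoods. Auxiliary drug similarities
    (GO-term cosine, ATC information-content/Resnik) can be combined with TOS by
    logistic regression, and a repeated cross-validated ROC harness evaluates how
    well the scores rank known combinations against random drug pairs. A
    synthetic-data module generates planted-partition networks, drugs,
    annotations and labeled cohorts so the whole pipeline runs without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
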