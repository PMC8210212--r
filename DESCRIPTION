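Package: sccircuits
Title: Mechanistic Signaling-Circuit Activity Analysis for Single-Cell
    Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers receptor-to-effector signaling circuit activities from
    single-cell gene expression by recursive propagation of normalized
    expression through signed pathway graphs, detects differentially active
    circuits between cell groups with an empirical-Bayes moderated t
    statistic, summarizes significant circuits by cancer hallmark, and
    simulates targeted drug perturbations per cell to separate responder
    from low-responder cells. Includes a dropout-aware consensus-cluster
    imputer for single-cell counts, a fully ground-truthed synthetic data
    generator (pathway graphs, clustered negative-binomial counts with
    expression-dependent dropout, planted differential circuits and a
    planted drug-resistant subpopulation), and readers/writers for the
    plain-text pathway, expression, gene-set and drug-table formats the
    pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    generics,
    cluster
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust
Config/testthat/edition: 3
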