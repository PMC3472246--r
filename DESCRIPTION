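Package: gluconet
Title: Deletion-Mutant Expression Compendium Analysis of the Yeast Glucose
    Regulatory System
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing compendia of yeast deletion-mutant
    expression profiles of the glucose signalling and storage-carbohydrate
    pathways: differential-expression calling against a wildtype reference
    pool, unsupervised partitioning of responsive mutants into high- and
    low-glucose mimicking groups, construction of a glucose gene signature
    by resampled KNN/leave-one-out selection, reconstruction of a directed
    hierarchical transcription network with sequential (L1/L2) and
    non-sequential (F1/F2) edge types calibrated by a permutation test,
    epistasis analysis of double-mutant profiles, and hypergeometric
    functional enrichment with Bonferroni correction. Includes a synthetic
    compendium generator with planted ground truth (groups, signature
    genes, typed edges, double mutants, glucose-addition time-courses) so
    the whole pipeline can be validated by recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
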