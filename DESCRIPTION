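Package: medivar
Title: Medium Versus Donor Variance Attribution for Primary-Cell
    Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies whether culture-medium composition or donor genetic
    background dominates primary-cell expression profiles from two-factor
    microarray-like intensity data. Implements housekeeping-gene
    normalization, negative-control detection-limit filtering with a
    three-criterion expression rule, sex-gene exclusion, pairwise
    differential expression with a replicate-swapping design and a
    moderated t-statistic (empirical-Bayes variance shrinkage with
    moment-matched hyperparameters), volcano classification,
    genome-wide and subset sample-structure analyses (hierarchical
    clustering, Spearman correlation, PCA, clustering purity),
    hypergeometric over-representation of gene sets, and a from-scratch
    preranked gene-set enrichment analysis with permutation-based
    normalized enrichment scores. A seeded synthetic-data generator
    emulating a 3-donor by 4-medium single-replicate design provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea
Config/testthat/edition: 3
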