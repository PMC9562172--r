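Package: tgem
Title: Interpretable Gene-Wise Self-Attention Models for Expression-Based
    Phenotype Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements T-GEM, a Transformer-style classifier for gene
    expression in which every gene carries its own scalar Query, Key and
    Value weights, so that attention is computed directly between named
    genes rather than between anonymous embedding dimensions. Provides
    model construction, seeded training with Adam on the multi-class
    negative log-likelihood, preprocessing (log transform, min-max
    scaling, highly variable gene selection, stratified splitting) and
    multi-class evaluation metrics (accuracy, Matthews correlation,
    macro one-vs-rest AUC). The interpretation toolkit covers attention
    entropy profiling, integrated-gradients attribution of attention
    weights, head and layer pruning diagnostics, per-head probe
    classifiers, extraction of directed Key-to-Query regulatory networks
    with hub-gene ranking, and hypergeometric geneset enrichment of
    informative genes. A synthetic-data generator with planted marker
    genes and correlated gene modules supports end-to-end validation,
    and readers/writers are included for expression TSV/CSV, MatrixMarket
    triplets, GMT genesets, SIF/GraphML networks and model checkpoints.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Matrix,
    igraph,
    e1071,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
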