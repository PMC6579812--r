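Package: drivefuse
Title: Cancer Driver Mutation Classification from Sequence Context and
    Functional Score Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies somatic single-nucleotide variants as cancer drivers or
    passengers by combining two complementary sources of evidence. A small
    convolutional neural network is trained on stacked reference/mutant
    nucleotide-context matrices extracted around each variant (label, one-hot
    or learned-embedding encodings), selected by stratified cross-validated
    grid search over a family of architectures, and its out-of-fold predicted
    driver probability (the "DL score") is fused with tabular functional and
    conservation feature columns in random-forest, gradient-boosted-tree and
    support-vector classifiers, with feature importance, recursive feature
    elimination and Spearman correlation analysis. Predicted driver positions
    can be post-processed on protein structures through residue interaction
    networks and normalized betweenness centrality. A synthetic-data module
    generates genomes, motif-planted variant sets and class-conditional score
    tables for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    vcfR,
    randomForest,
    xgboost,
    e1071,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
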