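Package: ginifano
Title: Cluster-Aware Weighted Ensemble Clustering for Rare and Common
    Cell Types in scRNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects both common and rare cell populations in UMI-based
    single-cell RNA-seq data by combining two complementary clustering
    stages into one consensus partition. A Gini-index stage selects genes
    whose expression is concentrated in few cells and clusters cells with
    DBSCAN on a Jaccard distance, which is sensitive to rare cell types. A
    Fano-factor stage selects highly variable genes and clusters cells with
    k-means on principal components, which resolves common cell types. The
    two partitions are merged through a cluster-aware weighted consensus
    association matrix in which each cell's weight is a logistic function
    of the size of the cluster it belongs to, so the rare-cell method
    dominates for small clusters and the common-cell method for large ones.
    The package also provides a negative-binomial count simulator with
    planted common and rare clusters, partition-agreement metrics (MCC,
    NMI, ARI, confusion maps), and a composite tSNE visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    Rtsne,
    stats,
    tibble,
    utils
Suggests:
    mclust,
    tidyr,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
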