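Package: rasnet
Title: Transcriptome-Weighted Metabolic Network Analysis with Reaction
    Activity Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-sample Reaction Activity Scores (RAS) on a
    metabolite-centric metabolic graph by evaluating gene-protein-reaction
    (GPR) rules over normalized RNA-seq expression, and provides three
    transition-probability adjustments that disambiguate reactions
    catalyzed by shared enzymes across parallel pathway series (such as
    the 0-, a-, b-, and c-series of ganglioside biosynthesis). Includes
    KGML and edge-table graph ingestion, median-of-ratios normalization,
    differential reaction activity analysis (log2 fold-change,
    Kolmogorov-Smirnov test, Benjamini-Hochberg correction), pathway-level
    activity aggregation, and unsupervised exploration via repeated UMAP
    embedding with HDBSCAN density clustering, cluster-stability
    summaries, internal validity indices, and marker-reaction detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    DESeq2,
    dplyr,
    generics,
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
    uwot,
    xml2,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
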