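Package: ctcseek
Title: Outlier-Sensitive Single-Cell RNA-Seq Detection of Circulating Tumor
    Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects rare circulating tumor cells (CTCs) among thousands of
    blood cells in droplet single-cell RNA-seq data. Implements a dual-pass
    analysis: an outlier-sensitive pass (uncapped gene scaling, no gene
    filtering, binned-dispersion highly-variable-gene selection without a
    lower expression bound, PCA with automated robust-z outlier calling,
    residual-based per-cell differential expression and preranked gene set
    enrichment analysis) and a robust pass for the non-outlier blood
    compartment (capped scaling, >=5-cell gene filter, kNN/Jaccard graph,
    Louvain modularity clustering, tSNE), plus cross-sample integration via
    canonical correlation analysis with quantile alignment, AUC and bimodal
    (hurdle) likelihood-ratio marker statistics, and a ground-truthed
    synthetic generator of blood with spiked hepatocyte-like rare cells.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    igraph,
    irlba,
    Rtsne,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    mclust,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
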