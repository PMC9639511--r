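Package: scHomology
Title: Cross-Species Single-Cell Cluster Homology via Preranked Gene-Set Enrichment
Version: 0.1.0
Authors@R:
    person("scHomology", "Authors", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Derives marker gene sets from source-species single-cell RNA-seq
    clusters (one-vs-rest Wilcoxon rank-sum tests with log fold changes), maps
    them through a user-supplied ortholog table, and scores their enrichment in
    signed-p ranked gene lists of target-species clusters with a from-scratch
    preranked gene-set enrichment analysis (weighted Kolmogorov-Smirnov running
    sum, gene-permutation null, normalized enrichment scores,
    Benjamini-Hochberg correction). Produces a source-by-target cluster
    homology matrix with best-match calls and a diverging heatmap. Includes a
    negative-binomial paired-dataset simulator with planted cluster
    correspondences so the full pipeline is testable without any download, and
    readers/writers for MTX, TSV, GMT, RNK and JSON artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    optparse,
    pheatmap,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
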