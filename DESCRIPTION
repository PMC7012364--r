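Package: lncoexnet
Title: Differential Expression and lncRNA-mRNA Coexpression Network
    Analysis for Three-Group Expression Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for studying malignant-transformation
    expression series with three tissue groups (control, dysplasia,
    carcinoma): empirical-Bayes moderated t-statistics for each pairwise
    contrast with Benjamini-Hochberg correction, GENCODE-based annotation
    of long noncoding RNA (lncRNA) probes, Pearson-threshold prediction of
    lncRNA target genes, shared-target lncRNA-lncRNA coregulation
    networks, hypergeometric gene-set over-representation, and
    correlation-distance hierarchical clustering.  Includes a synthetic
    data generator with planted differential expression and planted
    coexpression modules so every stage can be validated against known
    ground truth, plus readers and writers for GEO series-matrix, GTF,
    GMT, SIF and GraphML files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    igraph,
    jsonlite,
    yaml,
    ape,
    pheatmap,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    optparse
Config/testthat/edition: 3
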