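Package: spearnet
Title: Spearman Co-Expression Networks and Contiguous Gene Clusters for
    Condition-Series RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and mining of gene co-expression networks from
    bulk RNA-seq count matrices profiled across many cultivation conditions.
    Implements median-of-ratios library-size normalization with replicate
    averaging, expression-tier classification relative to a housekeeping
    reference, pairwise Spearman correlation with Benjamini-Hochberg FDR
    edge calling, top-k co-expression module extraction around a focal gene,
    signed embedded-regulator scoring for transcription-factor candidates,
    and detection of contiguous co-expressed gene clusters along genome
    coordinates. A negative-binomial simulator with planted correlation
    structure provides ground truth for calibration and recovery testing.
    Networks are exported in Cytoscape-loadable SIF and edge-table formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
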