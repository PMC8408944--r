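Package: sibflow
Title: Lineage-Resolved Analysis of Cell Fate Bifurcations in Single-Cell
    RNA-Seq
Version: 0.1.0
Authors@R:
    person("sibflow", "developers", email = "sibflow@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing cell fate bifurcations in lineage-resolved
    single-cell RNA-seq experiments on embryos derived from pooled,
    genetically distinct parents. Provides SNP-based mother-of-origin
    demultiplexing via pairwise genetic relatedness, a normalization
    backbone with maternal batch regression, Wilcoxon rank-sum
    differential expression, parent/sibling "trio" mechanism
    classification of differentially expressed transcription factors, a
    chi-square lineage-ablation sensitivity score with descendant
    propagation, an induction metric that predicts the signal-induced
    sibling, position-weight-matrix scanning with exact p-value
    calibration and binomial over-representation z-scores on dual
    promoter/open-chromatin region sets, and Ward clustering of temporal
    expression waves. A synthetic-data generator with machine-readable
    planted truth makes the entire pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
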