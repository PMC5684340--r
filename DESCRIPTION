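Package: EnhancerScape
Title: Differential Enhancer and Super-Enhancer Landscape Analysis from
    Histone-Mark ChIP-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calls co-occupied enhancers from replicated H3K27ac/H3K4me1
    peak sets, scores log2 ChIP-over-input enrichment, performs quantile
    normalization and an empirical-Bayes moderated two-group test with
    Benjamini-Hochberg adjustment to classify stimulus-regulated enhancers
    (including de novo gained and lost), identifies super-enhancers by
    ROSE-style stitching and rank-curve cutoff with gained/lost
    differential classification, integrates enhancer and super-enhancer
    changes with gene expression (TMM normalization, TPM, distance-based
    gene assignment, cumulative expression-contribution summaries), and
    tests lncRNA-enhancer overlap against a random-placement permutation
    null. Includes a seeded synthetic-data generator with planted truth so
    the whole pipeline is testable end to end, plus qPCR quantification
    utilities (delta-delta-Ct fold change and percent input).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    edgeR
Config/testthat/edition: 3
biocViews: Epigenetics, ChIPSeq, DifferentialPeakCalling, GeneRegulation,
    Normalization, Software
RoxygenNote: 7.3.3
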