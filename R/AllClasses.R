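#' @import methods
#' @importFrom GenomicRanges GRanges granges reduce findOverlaps countOverlaps
#' @importFrom IRanges IRanges subsetByOverlaps overlapsAny
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<- queryHits
#'   subjectHits
#' @importFrom GenomeInfoDb Seqinfo seqlengths seqnames seqinfo seqlevels
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowRanges
NULL

#' ChIP-seq sample track
#'
#' Bundles everything the pipeline needs to know about one sequencing sample:
#' its peak calls, its fragment placements (each paired-end fragment as a
#' single genomic interval, counted once), the library size used for
#' per-million scaling, and the design metadata (mark, condition, replicate)
#' plus the identifier of its matched input sample.
#'
#' @slot sampleId character(1), unique sample identifier.
#' @slot mark one of "H3K27ac", "H3K4me1", "H3K4me3", "BRD4", "input".
#' @slot condition "control" or "treated" ("input" tracks keep the condition
#'   they were sequenced in).
#' @slot replicate integer replicate number.
#' @slot peaks GRanges of peak calls (may be empty).
#' @slot fragments GRanges of fragment spans (may be empty when only peaks
#'   are available).
#' @slot librarySize numeric(1), total fragment count of the library; must be
#'   positive when fragments are present.
#' @slot inputId character(1), sampleId of the matched input track, or NA for
#'   input tracks themselves.
#' @exportClass SampleTrack
setClass("SampleTrack",
    slots = c(
        sampleId = "character",
        mark = "character",
        condition = "character",
        replicate = "integer",
        peaks = "GRanges",
        fragments = "GRanges",
        librarySize = "numeric",
        inputId = "character"
    )
)

setValidity("SampleTrack", function(object) {
    msg <- NULL
    marks <- c("H3K27ac", "H3K4me1", "H3K4me3", "BRD4", "input")
    if (!object@mark %in% marks)
        msg <- c(msg, sprintf("mark must be one of %s",
                              paste(marks, collapse = ", ")))
    if (!object@condition %in% c("control", "treated"))
        msg <- c(msg, "condition must be 'control' or 'treated'")
    if (length(object@fragments) > 0 &&
        (!is.finite(object@librarySize) || object@librarySize <= 0))
        msg <- c(msg, "librarySize must be > 0 when fragments are present")
    if (is.null(msg)) TRUE else msg
})

#' Construct a SampleTrack
#'
#' @param sampleId unique sample identifier.
#' @param mark assayed mark ("H3K27ac", "H3K4me1", "H3K4me3", "BRD4",
#'   "input").
#' @param condition "control" or "treated".
#' @param replicate replicate number.
#' @param peaks GRanges of peak calls.
#' @param fragments GRanges of fragment spans.
#' @param librarySize total fragments in the library; defaults to
#'   `length(fragments)` when fragments are supplied.
#' @param inputId sampleId of the matched input track (NA for inputs).
#' @return A [SampleTrack-class] object.
#' @export
sampleTrack <- function(sampleId, mark, condition, replicate = 1L,
                        peaks = GRanges(), fragments = GRanges(),
                        librarySize = NA_real_, inputId = NA_character_) {
    if (is.na(librarySize) && length(fragments) > 0)
        librarySize <- length(fragments)
    new("SampleTrack", sampleId = as.character(sampleId),
        mark = as.character(mark), condition = as.character(condition),
        replicate = as.integer(replicate), peaks = peaks,
        fragments = fragments, librarySize = as.numeric(librarySize),
        inputId = as.character(inputId))
}

setMethod("show", "SampleTrack", function(object) {
    cat(sprintf("SampleTrack '%s': %s / %s / rep %d\n", object@sampleId,
                object@mark, object@condition, object@replicate))
    cat(sprintf("  %d peaks, %d fragments (library size %s)\n",
                length(object@peaks), length(object@fragments),
                format(object@librarySize, big.mark = ",")))
})

#' Gene annotation
#'
#' Per-gene TSS, strand and exon structure. The TSS is the first transcribed
#' base (1-based internally); `gene_length` is the total exonic width.
#'
#' @slot genes GRanges spanning each gene body, with metadata columns
#'   `gene_id`, `tss` (1-based position) and `gene_length`.
#' @slot exons GRangesList of exons, one element per gene, names matching
#'   `gene_id`.
#' @exportClass GeneAnnotation
setClass("GeneAnnotation",
    slots = c(genes = "GRanges", exons = "CompressedGRangesList")
)

setValidity("GeneAnnotation", function(object) {
    msg <- NULL
    need <- c("gene_id", "tss", "gene_length")
    if (!all(need %in% colnames(mcols(object@genes))))
        msg <- c(msg, sprintf("genes must carry mcols %s",
                              paste(need, collapse = ", ")))
    else {
        if (length(object@exons) != length(object@genes))
            msg <- c(msg, "one exon set per gene required")
        if (any(mcols(object@genes)$gene_length <= 0))
            msg <- c(msg, "gene_length must be positive")
    }
    if (is.null(msg)) TRUE else msg
})

#' @param genes,exons see slot documentation.
#' @rdname GeneAnnotation-class
#' @export
geneAnnotation <- function(genes, exons) {
    if (is.list(exons)) {
        # harmonize per-gene seqlevels so the list coercion never warns
        lv <- Reduce(union, lapply(exons, GenomeInfoDb::seqlevels),
                     GenomeInfoDb::seqlevels(genes))
        exons <- lapply(exons, function(e) {
            GenomeInfoDb::seqlevels(e) <- lv
            e
        })
    }
    new("GeneAnnotation", genes = genes,
        exons = methods::as(exons, "CompressedGRangesList"))
}

setMethod("show", "GeneAnnotation", function(object) {
    cat(sprintf("GeneAnnotation with %d genes on %d sequence(s)\n",
                length(object@genes),
                length(unique(as.character(seqnames(object@genes))))))
})

#' Enhancer catalog
#'
#' The co-occupied, regulatory-region-filtered enhancer set: merged H3K27ac
#' regions supported by at least `minSupport` samples that overlap an
#' H3K4me1-supported region, with promoter/exon/H3K4me3-overlapping regions
#' removed.
#'
#' @slot enhancers GRanges with metadata columns `support_ac` and
#'   `support_me1`.
#' @slot filtersApplied character vector naming the exclusion filters that
#'   have been applied.
#' @slot filterCounts named integer vector: regions removed by each filter.
#' @exportClass EnhancerCatalog
setClass("EnhancerCatalog",
    slots = c(
        enhancers = "GRanges",
        filtersApplied = "character",
        filterCounts = "integer"
    )
)

setValidity("EnhancerCatalog", function(object) {
    need <- c("support_ac", "support_me1")
    if (!all(need %in% colnames(mcols(object@enhancers))))
        return(sprintf("enhancers must carry mcols %s",
                       paste(need, collapse = ", ")))
    TRUE
})

setMethod("show", "EnhancerCatalog", function(object) {
    cat(sprintf("EnhancerCatalog with %d enhancers\n",
                length(object@enhancers)))
    if (length(object@filtersApplied))
        cat("  filters applied:",
            paste(object@filtersApplied, collapse = ", "), "\n")
    if (length(object@filterCounts))
        cat("  removed:",
            paste(sprintf("%s=%d", names(object@filterCounts),
                          object@filterCounts), collapse = ", "), "\n")
})

#' Enhancer enrichment matrix
#'
#' A RangedSummarizedExperiment whose rows are enhancers and columns ChIP
#' samples, with assays `chip` and `input` (per-million-scaled fragment
#' counts) and `enrichment` (log2 of (chip+1)/(input+1)). The metadata flag
#' `normalized` records whether quantile normalization has been applied to
#' the enrichment assay.
#'
#' @exportClass EnhancerEnrichment
setClass("EnhancerEnrichment", contains = "RangedSummarizedExperiment")

setValidity("EnhancerEnrichment", function(object) {
    msg <- NULL
    need <- c("chip", "input", "enrichment")
    if (!all(need %in% names(assays(object))))
        msg <- c(msg, sprintf("assays %s required",
                              paste(need, collapse = ", ")))
    if (!all(c("condition", "replicate") %in% colnames(colData(object))))
        msg <- c(msg, "colData must contain condition and replicate")
    else if (!all(colData(object)$condition %in% c("control", "treated")))
        msg <- c(msg, "condition must be control/treated")
    if (!is.null(msg)) return(msg)
    if (any(!is.finite(assay(object, "enrichment"))))
        return("enrichment values must all be finite")
    TRUE
})

setMethod("show", "EnhancerEnrichment", function(object) {
    cat(sprintf(
        "EnhancerEnrichment: %d enhancers x %d samples (%s)\n",
        nrow(object), ncol(object),
        if (isTRUE(metadata(object)$normalized)) "quantile-normalized"
        else "raw enrichment"))
    cat("  conditions:",
        paste(sprintf("%s=%d", names(table(colData(object)$condition)),
                      table(colData(object)$condition)), collapse = ", "),
        "\n")
})

#' ROSE-style super-enhancer ranking
#'
#' Stitched enhancer regions ranked by ascending background-subtracted
#' signal, with the rank-curve tangency cutoff and super-enhancer flags.
#'
#' @slot regions GRanges sorted by ascending signal with metadata columns
#'   `signal`, `rank`, `isSE` and `nConstituents`.
#' @slot cutoffSignal numeric(1) signal at the tangency point; regions with
#'   signal strictly above it are super-enhancers.
#' @slot condition character(1) label of the condition ranked.
#' @exportClass RoseRanking
setClass("RoseRanking",
    slots = c(
        regions = "GRanges",
        cutoffSignal = "numeric",
        condition = "character"
    )
)

setValidity("RoseRanking", function(object) {
    need <- c("signal", "rank", "isSE")
    if (length(object@regions) == 0) return(TRUE)
    if (!all(need %in% colnames(mcols(object@regions))))
        return(sprintf("regions must carry mcols %s",
                       paste(need, collapse = ", ")))
    sig <- mcols(object@regions)$signal
    se <- mcols(object@regions)$isSE
    if (is.unsorted(sig)) return("regions must be sorted by ascending signal")
    # SEs must be a contiguous top-signal suffix
    if (any(se) && !all(se[seq(which(se)[1], length(se))]))
        return("SE flags must form a contiguous top-signal suffix")
    TRUE
})

setMethod("show", "RoseRanking", function(object) {
    n <- length(object@regions)
    nse <- sum(mcols(object@regions)$isSE %||% logical(0))
    cat(sprintf(
        "RoseRanking (%s): %d stitched regions, %d SEs (cutoff %.3f rpm)\n",
        object@condition, n, nse, object@cutoffSignal))
})

#' lncRNA-enhancer overlap permutation test result
#'
#' @slot observedEnhancers integer(1) enhancers overlapping >= 1 lncRNA.
#' @slot observedLncrnas integer(1) lncRNAs overlapping >= 1 enhancer.
#' @slot nullCounts integer vector of simulated enhancer-side overlap counts.
#' @slot pValue add-one empirical p-value for the enhancer-side count.
#' @slot nEnhancers,nLncrnas,genomeLength problem dimensions.
#' @exportClass OverlapTestResult
setClass("OverlapTestResult",
    slots = c(
        observedEnhancers = "integer",
        observedLncrnas = "integer",
        nullCounts = "integer",
        pValue = "numeric",
        nEnhancers = "integer",
        nLncrnas = "integer",
        genomeLength = "numeric"
    )
)

setValidity("OverlapTestResult", function(object) {
    msg <- NULL
    if (object@observedEnhancers < 0 ||
        object@observedEnhancers > object@nEnhancers)
        msg <- c(msg, "observed count must lie in [0, nEnhancers]")
    if (length(object@pValue) &&
        (object@pValue <= 0 || object@pValue > 1))
        msg <- c(msg, "p must lie in (0, 1]")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "OverlapTestResult", function(object) {
    cat(sprintf(
        "OverlapTestResult: %d/%d enhancers overlap a lncRNA (%d lncRNAs)\n",
        object@observedEnhancers, object@nEnhancers, object@nLncrnas))
    cat(sprintf("  null: %d simulations, mean %.2f, sd %.2f\n",
                length(object@nullCounts), mean(object@nullCounts),
                stats::sd(object@nullCounts)))
    cat(sprintf("  add-one empirical p = %.4g\n", object@pValue))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
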