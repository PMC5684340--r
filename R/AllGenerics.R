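#' Extract the genomic regions of an object
#'
#' @param x an EnhancerCatalog, RoseRanking or GeneAnnotation.
#' @return A GRanges.
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' @rdname regions
#' @export
setMethod("regions", "EnhancerCatalog", function(x) x@enhancers)

#' @rdname regions
#' @export
setMethod("regions", "RoseRanking", function(x) x@regions)

#' @rdname regions
#' @export
setMethod("regions", "GeneAnnotation", function(x) x@genes)

#' Exon structure of a gene annotation
#'
#' @param x a GeneAnnotation.
#' @return A GRangesList, one element per gene.
#' @export
setGeneric("geneExons", function(x) standardGeneric("geneExons"))

#' @rdname geneExons
#' @export
setMethod("geneExons", "GeneAnnotation", function(x) x@exons)

#' Super-enhancer cutoff signal
#'
#' @param x a RoseRanking.
#' @return numeric(1), the signal at the rank-curve tangency point.
#' @export
setGeneric("cutoffSignal", function(x) standardGeneric("cutoffSignal"))

#' @rdname cutoffSignal
#' @export
setMethod("cutoffSignal", "RoseRanking", function(x) x@cutoffSignal)

#' Super-enhancer flags
#'
#' @param x a RoseRanking.
#' @return logical vector parallel to `regions(x)`.
#' @export
setGeneric("isSE", function(x) standardGeneric("isSE"))

#' @rdname isSE
#' @export
setMethod("isSE", "RoseRanking", function(x) mcols(x@regions)$isSE)

#' Empirical p-value of a permutation test
#'
#' @param x an OverlapTestResult.
#' @return numeric(1).
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname pValue
#' @export
setMethod("pValue", "OverlapTestResult", function(x) x@pValue)

#' Null distribution of a permutation test
#'
#' @param x an OverlapTestResult.
#' @return integer vector of simulated overlap counts.
#' @export
setGeneric("nullCounts", function(x) standardGeneric("nullCounts"))

#' @rdname nullCounts
#' @export
setMethod("nullCounts", "OverlapTestResult", function(x) x@nullCounts)
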