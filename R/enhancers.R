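#' Call candidate co-occupied enhancers
#'
#' Merges all H3K27ac peaks across samples, keeps merged regions supported
#' by at least `minSupport` samples, and retains those that overlap (>= 1
#' bp) a merged H3K4me1 region that is itself supported by at least
#' `minSupport` samples. The returned footprint is the H3K27ac merged
#' region, since all downstream quantification is H3K27ac-based.
#'
#' @param acPeaks list of per-sample H3K27ac peak GRanges (one per sample,
#'   both conditions and replicates).
#' @param me1Peaks list of per-sample H3K4me1 peak GRanges; must have the
#'   same number of samples as `acPeaks`.
#' @param minSupport minimum number of supporting samples per mark
#'   (default 2).
#' @return GRanges of candidate enhancers with metadata columns
#'   `support_ac` and `support_me1` (the maximal support of any overlapping
#'   H3K4me1 region).
#' @export
callCandidateEnhancers <- function(acPeaks, me1Peaks, minSupport = 2) {
    if (!is.list(acPeaks) || !is.list(me1Peaks) ||
        length(acPeaks) != length(me1Peaks))
        stop("acPeaks and me1Peaks must be lists with matching sample counts")
    acMerged <- mergeIntervals(do.call(c, unname(acPeaks)))
    acSupport <- countSupport(acMerged, acPeaks)
    acMerged <- acMerged[acSupport >= minSupport]
    acSupport <- acSupport[acSupport >= minSupport]
    me1Merged <- mergeIntervals(do.call(c, unname(me1Peaks)))
    me1Support <- countSupport(me1Merged, me1Peaks)
    me1Ok <- me1Merged[me1Support >= minSupport]
    me1OkSupport <- me1Support[me1Support >= minSupport]
    hm <- .sameLevels(acMerged, me1Ok)
    hits <- findOverlaps(hm$q, hm$s, ignore.strand = TRUE)
    keep <- unique(queryHits(hits))
    out <- acMerged[keep]
    mcols(out)$support_ac <- acSupport[keep]
    bestMe1 <- tapply(me1OkSupport[subjectHits(hits)], queryHits(hits), max)
    mcols(out)$support_me1 <- as.integer(bestMe1[as.character(keep)])
    out
}

#' Exclude promoter, exon and H3K4me3-overlapping candidates
#'
#' Removes every candidate region overlapping (>= 1 bp) a promoter window
#' (TSS +/- `promoterFlank` bp), an annotated exon, or an H3K4me3 peak, in
#' that order, and returns the surviving enhancer catalog.
#'
#' @param candidates GRanges from [callCandidateEnhancers()].
#' @param annotation a [GeneAnnotation-class].
#' @param k4me3Peaks GRanges of H3K4me3 peaks (merged or raw).
#' @param promoterFlank promoter half-width in bp (default 1000).
#' @return An [EnhancerCatalog-class].
#' @export
filterRegulatory <- function(candidates, annotation, k4me3Peaks,
                             promoterFlank = 1000) {
    prom <- promoterWindows(annotation, promoterFlank)
    exons <- unlist(geneExons(annotation), use.names = FALSE)
    inProm <- .overlapsAny(candidates, prom)
    kept <- candidates[!inProm]
    inExon <- .overlapsAny(kept, exons)
    kept2 <- kept[!inExon]
    inK4 <- .overlapsAny(kept2, k4me3Peaks)
    out <- kept2[!inK4]
    new("EnhancerCatalog", enhancers = out,
        filtersApplied = c("promoter", "exon", "H3K4me3"),
        filterCounts = c(promoter = sum(inProm), exon = sum(inExon),
                         H3K4me3 = sum(inK4)))
}

#' Compute the log2 ChIP-over-input enrichment matrix
#'
#' For each enhancer and each ChIP sample of the requested mark, counts
#' fragments scaled to one million total fragments in both the ChIP and its
#' matched input sample and forms
#' `E = log2((Count_ChIP + 1) / (Count_input + 1))`.
#'
#' @param catalog an [EnhancerCatalog-class] (or plain GRanges).
#' @param tracks named list of [SampleTrack-class], containing the ChIP
#'   samples of `mark` and every input sample they reference.
#' @param mark which ChIP mark to quantify (default "H3K27ac").
#' @return An [EnhancerEnrichment-class] with assays `chip`, `input`,
#'   `enrichment`.
#' @export
computeEnrichment <- function(catalog, tracks, mark = "H3K27ac") {
    gr <- if (is(catalog, "EnhancerCatalog")) regions(catalog) else catalog
    chip <- Filter(function(t) t@mark == mark, tracks)
    if (length(chip) == 0)
        stop(sprintf("no tracks with mark '%s'", mark))
    ids <- vapply(tracks, function(t) t@sampleId, character(1))
    chipMat <- inputMat <- matrix(0, nrow = length(gr), ncol = length(chip))
    cd <- data.frame(sampleId = character(length(chip)),
                     condition = character(length(chip)),
                     replicate = integer(length(chip)),
                     stringsAsFactors = FALSE)
    for (j in seq_along(chip)) {
        t <- chip[[j]]
        if (is.na(t@inputId) || !t@inputId %in% ids)
            stop(sprintf("sample '%s' has no matched input sample",
                         t@sampleId))
        inputTrack <- tracks[[which(ids == t@inputId)[1]]]
        chipMat[, j] <- scaledRegionCounts(gr, t)
        inputMat[, j] <- scaledRegionCounts(gr, inputTrack)
        cd$sampleId[j] <- t@sampleId
        cd$condition[j] <- t@condition
        cd$replicate[j] <- t@replicate
    }
    colnames(chipMat) <- colnames(inputMat) <- cd$sampleId
    enr <- log2((chipMat + 1) / (inputMat + 1))
    se <- SummarizedExperiment(
        assays = list(chip = chipMat, input = inputMat, enrichment = enr),
        rowRanges = gr, colData = DataFrame(cd, row.names = cd$sampleId))
    metadata(se)$normalized <- FALSE
    new("EnhancerEnrichment", se)
}

#' Quantile normalization
#'
#' Forces every column of a matrix to the identical empirical distribution:
#' the per-rank means of the sorted input columns. Within-column rank order
#' is preserved and ties receive the mean of the tied ranks' reference
#' values (midrank interpolation).
#'
#' @param x numeric matrix (features x samples) or an
#'   [EnhancerEnrichment-class], whose `enrichment` assay is normalized in
#'   place (setting the `normalized` metadata flag).
#' @return Same class as the input.
#' @export
setGeneric("quantileNormalize", function(x) standardGeneric("quantileNormalize"))

#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "matrix", function(x) {
    if (ncol(x) < 2) {
        warning("single column: returned unchanged")
        return(x)
    }
    ref <- rowMeans(apply(x, 2, sort))
    n <- nrow(x)
    out <- apply(x, 2, function(col) {
        r <- rank(col, ties.method = "average")
        # fractional midranks interpolate between adjacent reference values
        stats::approx(seq_len(n), ref, xout = r)$y
    })
    dimnames(out) <- dimnames(x)
    out
})

#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "EnhancerEnrichment", function(x) {
    SummarizedExperiment::assay(x, "enrichment") <-
        quantileNormalize(assay(x, "enrichment"))
    metadata(x)$normalized <- TRUE
    validObject(x)
    x
})
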