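#' Merge genomic intervals into a disjoint set
#'
#' Computes the coverage union of a set of intervals: overlapping intervals
#' are merged and abutting intervals (zero-length gap) are joined, so the
#' result is sorted and pairwise disjoint with the union of covered bases
#' preserved. Strand is ignored throughout enhancer arithmetic.
#'
#' @param x GRanges to merge.
#' @param layout optional Seqinfo; when supplied, intervals extending past
#'   their chromosome end raise an error naming the interval.
#' @return A sorted, disjoint GRanges.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 51), c(100, 150)))
#' mergeIntervals(gr)
#' @export
mergeIntervals <- function(x, layout = NULL) {
    if (!is.null(layout)) checkBounds(x, layout)
    reduce(sort(GRanges(seqnames(x), IRanges::ranges(x))),
           min.gapwidth = 1L)
}

# match seqlevels of two GRanges so overlap operations never warn about
# disjoint sequence universes (toy inputs often carry only one chromosome)
.sameLevels <- function(q, s) {
    lv <- union(GenomeInfoDb::seqlevels(q), GenomeInfoDb::seqlevels(s))
    GenomeInfoDb::seqlevels(q) <- lv
    GenomeInfoDb::seqlevels(s) <- lv
    list(q = q, s = s)
}

.countOv <- function(q, s) {
    h <- .sameLevels(q, s)
    countOverlaps(h$q, h$s, ignore.strand = TRUE)
}

.overlapsAny <- function(q, s) .countOv(q, s) > 0

checkBounds <- function(x, layout) {
    if (length(x) == 0) return(invisible(TRUE))
    sl <- seqlengths(layout)
    chrom <- as.character(seqnames(x))
    bad <- !(chrom %in% names(sl))
    if (!any(bad)) bad <- GenomicRanges::end(x) > sl[chrom]
    if (any(bad)) {
        i <- which(bad)[1]
        stop(sprintf("interval %s:%d-%d lies outside chromosome bounds",
                     chrom[i], GenomicRanges::start(x)[i],
                     GenomicRanges::end(x)[i]))
    }
    invisible(TRUE)
}

#' Count per-sample support for merged regions
#'
#' For each merged region, counts how many samples have at least one peak
#' overlapping it by >= 1 bp. The result is invariant to sample order.
#'
#' @param merged disjoint GRanges (typically from [mergeIntervals()]).
#' @param peakSets list of per-sample peak GRanges.
#' @return Integer vector of support counts, one per merged region.
#' @export
countSupport <- function(merged, peakSets) {
    stopifnot(is.list(peakSets))
    if (length(merged) == 0) return(integer(0))
    support <- integer(length(merged))
    for (ps in peakSets)
        support <- support + as.integer(.overlapsAny(merged, ps))
    support
}

#' Per-region fragment counts scaled to one million total fragments
#'
#' A fragment counts once towards every region it overlaps by >= 1 bp;
#' counts are scaled by 1e6 / library size, so a library of exactly one
#' million fragments returns raw counts.
#'
#' @param regions GRanges to quantify.
#' @param track a [SampleTrack-class] with fragments and a positive library
#'   size.
#' @return Numeric vector of per-million-scaled counts.
#' @export
scaledRegionCounts <- function(regions, track) {
    stopifnot(is(track, "SampleTrack"))
    if (!is.finite(track@librarySize) || track@librarySize <= 0)
        stop(sprintf("sample '%s': library size must be positive",
                     track@sampleId))
    raw <- .countOv(regions, track@fragments)
    raw * 1e6 / track@librarySize
}

#' Genomic distribution of regions relative to gene annotation
#'
#' Assigns each region to exactly one category with priority
#' promoter > exon > intron > intergenic, where a promoter is the TSS plus
#' or minus `promoterFlank` bp, an exon hit is >= 1 bp overlap with any
#' annotated exon, and an intron hit is an overlap with a gene body outside
#' exons and promoters.
#'
#' @param x GRanges of regions.
#' @param annotation a [GeneAnnotation-class].
#' @param promoterFlank promoter half-width in bp (default 1000).
#' @return A list with `counts` (named integer) and `fractions` (named
#'   numeric summing to 1); both empty-safe.
#' @export
genomicDistribution <- function(x, annotation, promoterFlank = 1000) {
    categories <- c("promoter", "exon", "intron", "intergenic")
    if (length(x) == 0) {
        z <- stats::setNames(integer(4), categories)
        return(list(counts = z, fractions = stats::setNames(numeric(4),
                                                            categories)))
    }
    prom <- promoterWindows(annotation, promoterFlank)
    exons <- unlist(geneExons(annotation), use.names = FALSE)
    bodies <- regions(annotation)
    inProm <- .overlapsAny(x, prom)
    inExon <- !inProm & .overlapsAny(x, exons)
    inIntr <- !inProm & !inExon & .overlapsAny(x, bodies)
    cat <- rep("intergenic", length(x))
    cat[inIntr] <- "intron"
    cat[inExon] <- "exon"
    cat[inProm] <- "promoter"
    counts <- stats::setNames(
        vapply(categories, function(k) sum(cat == k), integer(1)), categories)
    list(counts = counts, fractions = counts / length(x))
}

#' Promoter windows around annotated TSSs
#'
#' @param annotation a [GeneAnnotation-class].
#' @param flank half-width in bp.
#' @return GRanges of TSS +/- flank windows (clipped at position 1).
#' @export
promoterWindows <- function(annotation, flank = 1000) {
    g <- regions(annotation)
    tss <- mcols(g)$tss
    GRanges(seqnames(g),
            IRanges(start = pmax(1, tss - flank), end = tss + flank))
}
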