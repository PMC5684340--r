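#' Read a BED3/BED6 file
#'
#' Reads tab-separated, headerless BED with 0-based half-open coordinates
#' into a GRanges (1-based closed internally, as is standard for Bioconductor
#' containers; coordinates written back out by [writeBed()] round-trip
#' unchanged). Malformed lines raise an error naming the line number.
#'
#' @param path file path.
#' @return A GRanges; a `name` metadata column is kept when present.
#' @export
readBed <- function(path) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) return(GRanges())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3))
        stop(sprintf("%s: malformed BED line %d (fewer than 3 fields)",
                     path, which(nf < 3)[1]))
    chrom <- vapply(fields, `[[`, character(1), 1)
    start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2)))
    end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3)))
    bad <- is.na(start) | is.na(end) | start < 0 | start >= end
    if (any(bad))
        stop(sprintf("%s: malformed BED line %d (invalid coordinates)",
                     path, which(bad)[1]))
    gr <- GRanges(chrom, IRanges(start = start + 1, end = end))
    if (all(nf >= 4))
        mcols(gr)$name <- vapply(fields, `[[`, character(1), 4)
    if (all(nf >= 6)) {
        s <- vapply(fields, `[[`, character(1), 6)
        s[!s %in% c("+", "-")] <- "*"
        GenomicRanges::strand(gr) <- s
    }
    gr
}

#' Write a GRanges as BED
#'
#' Emits tab-separated BED (0-based half-open), byte-for-byte reproducible
#' for a given input. Extra numeric columns can be appended after the
#' standard fields.
#'
#' @param x GRanges to write.
#' @param path output path.
#' @param extraCols optional named list/data.frame of extra columns.
#' @return Invisibly, the path.
#' @export
writeBed <- function(x, path, extraCols = NULL) {
    df <- data.frame(
        chrom = as.character(seqnames(x)),
        start = format(GenomicRanges::start(x) - 1, scientific = FALSE,
                       trim = TRUE),
        end = format(GenomicRanges::end(x), scientific = FALSE, trim = TRUE),
        stringsAsFactors = FALSE)
    if ("name" %in% colnames(mcols(x))) df$name <- mcols(x)$name
    if (!is.null(extraCols)) df <- cbind(df, as.data.frame(extraCols))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read/write chromosome sizes
#'
#' Two-column tab-separated file: chromosome name, length in bp.
#'
#' @param path file path.
#' @return `readChromSizes()`: a Seqinfo layout.
#' @export
readChromSizes <- function(path) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("chrom", "length"),
                            stringsAsFactors = FALSE)
    genomeLayout(stats::setNames(df$length, df$chrom))
}

#' @param layout a Seqinfo layout to write.
#' @rdname readChromSizes
#' @export
writeChromSizes <- function(layout, path) {
    df <- data.frame(chrom = seqnames(layout),
                     length = format(seqlengths(layout), scientific = FALSE,
                                     trim = TRUE))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read/write gene annotation tables
#'
#' Tab-separated with header, columns: gene_id, chrom, strand, tss (0-based
#' position of the first transcribed base), exon_starts, exon_ends
#' (comma-separated 0-based half-open), gene_length (total exonic bp).
#'
#' @param path file path.
#' @return `readGeneAnnotation()`: a [GeneAnnotation-class].
#' @export
readGeneAnnotation <- function(path) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "strand", "tss", "exon_starts",
              "exon_ends", "gene_length")
    if (!all(need %in% colnames(df)))
        stop(sprintf("gene annotation must have columns: %s",
                     paste(need, collapse = ", ")))
    exonList <- lapply(seq_len(nrow(df)), function(i) {
        s <- as.numeric(strsplit(df$exon_starts[i], ",")[[1]])
        e <- as.numeric(strsplit(df$exon_ends[i], ",")[[1]])
        GRanges(df$chrom[i], IRanges(start = s + 1, end = e),
                strand = df$strand[i])
    })
    names(exonList) <- df$gene_id
    spans <- GRanges(df$chrom,
                     IRanges(start = vapply(exonList, function(g)
                                 min(GenomicRanges::start(g)), numeric(1)),
                             end = vapply(exonList, function(g)
                                 max(GenomicRanges::end(g)), numeric(1))),
                     strand = df$strand)
    mcols(spans)$gene_id <- df$gene_id
    mcols(spans)$tss <- df$tss + 1
    mcols(spans)$gene_length <- df$gene_length
    geneAnnotation(spans, exonList)
}

#' @param annotation a [GeneAnnotation-class] to write.
#' @rdname readGeneAnnotation
#' @export
writeGeneAnnotation <- function(annotation, path) {
    g <- regions(annotation)
    ex <- geneExons(annotation)
    fmtPos <- function(v) format(v, scientific = FALSE, trim = TRUE)
    df <- data.frame(
        gene_id = mcols(g)$gene_id,
        chrom = as.character(seqnames(g)),
        strand = as.character(GenomicRanges::strand(g)),
        tss = fmtPos(mcols(g)$tss - 1),
        exon_starts = vapply(seq_along(ex), function(i)
            paste(fmtPos(GenomicRanges::start(ex[[i]]) - 1), collapse = ","),
            character(1)),
        exon_ends = vapply(seq_along(ex), function(i)
            paste(fmtPos(GenomicRanges::end(ex[[i]])), collapse = ","),
            character(1)),
        gene_length = mcols(g)$gene_length,
        stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write a region-by-sample numeric matrix as TSV
#'
#' First three columns are BED-style chrom/start/end, then one column per
#' sample.
#'
#' @param regions GRanges of rows.
#' @param mat numeric matrix with one column per sample.
#' @param path output path.
#' @export
writeRegionMatrix <- function(regions, mat, path) {
    df <- data.frame(
        chrom = as.character(seqnames(regions)),
        start = GenomicRanges::start(regions) - 1,
        end = GenomicRanges::end(regions),
        stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(mat))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
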