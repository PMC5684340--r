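#' Classify differential enhancers
#'
#' Labels each enhancer from its moderated-test results: `up` when logFC >=
#' `logfcThreshold` and q < `qThreshold`, `down` for the mirror image,
#' `unaffected_background` when the linear fold change is within the
#' low-change band (|logFC| <= log2(`backgroundBand`)), and `other`
#' otherwise. Fold change >= 2 on the log2 enrichment scale is a difference
#' of >= 1 log2 unit. Enhancers with missing statistics are labelled
#' `other`.
#'
#' @param table data.frame with columns logFC and q (see
#'   [moderatedTTest()] and [bhAdjust()]).
#' @param logfcThreshold log2 difference threshold (default 1, i.e. linear
#'   fold 2).
#' @param qThreshold BH-adjusted significance level (default 0.05).
#' @param backgroundBand linear fold bound of the unaffected background
#'   band (default 1.05).
#' @return character vector of class labels.
#' @export
classifyDifferential <- function(table, logfcThreshold = 1,
                                 qThreshold = 0.05,
                                 backgroundBand = 1.05) {
    lfc <- table$logFC
    q <- table$q
    cls <- rep("other", nrow(table))
    cls[abs(lfc) <= log2(backgroundBand)] <- "unaffected_background"
    ok <- !is.na(q)
    cls[ok & lfc >= logfcThreshold & q < qThreshold] <- "up"
    cls[ok & lfc <= -logfcThreshold & q < qThreshold] <- "down"
    cls
}

#' Flag de novo gained and lost enhancers
#'
#' Among enhancers already classified differential, a `de_novo_gained`
#' enhancer has mean treated enrichment above `gainedHi` with mean control
#' enrichment below `flatLo`; `de_novo_lost` is the mirror image. By
#' default the thresholds apply to the log2 enrichment E (the same scale
#' the moderated test uses); `scale = "linear"` instead applies them to the
#' linear (Count_ChIP+1)/(Count_input+1) ratio, i.e. 2^E.
#'
#' @param table data.frame with columns class (from
#'   [classifyDifferential()]), meanCtrl and meanTrt.
#' @param gainedHi upper enrichment threshold (default 1.5).
#' @param flatLo lower enrichment threshold (default 1.1).
#' @param scale "log2" (default) or "linear".
#' @return character vector of class labels with de novo labels substituted
#'   where the thresholds are met.
#' @export
classifyDeNovo <- function(table, gainedHi = 1.5, flatLo = 1.1,
                           scale = c("log2", "linear")) {
    scale <- match.arg(scale)
    mc <- table$meanCtrl
    mt <- table$meanTrt
    if (scale == "linear") {
        mc <- 2^mc
        mt <- 2^mt
    }
    cls <- table$class
    cls[cls == "up" & mt > gainedHi & mc < flatLo] <- "de_novo_gained"
    cls[cls == "down" & mt < flatLo & mc > gainedHi] <- "de_novo_lost"
    cls
}

#' Differential enhancer analysis
#'
#' End-to-end differential test on an enrichment matrix: quantile
#' normalization (optional but on by default), moderated two-group test,
#' BH adjustment, differential classification and de novo labelling.
#'
#' @param enrichment an [EnhancerEnrichment-class].
#' @param normalize quantile-normalize before testing (default TRUE).
#' @param logfcThreshold,qThreshold,backgroundBand see
#'   [classifyDifferential()].
#' @param deNovoHi,deNovoLo,deNovoScale see [classifyDeNovo()].
#' @param d0 variance-prior degrees of freedom, see [moderatedTTest()].
#' @return GRanges of the enhancers with metadata columns logFC, t, p, q,
#'   class, meanCtrl, meanTrt; the estimated variance prior is attached as
#'   attribute `ebayes` (list with d0 and s0sq).
#' @export
differentialEnhancers <- function(enrichment, normalize = TRUE,
                                  logfcThreshold = 1, qThreshold = 0.05,
                                  backgroundBand = 1.05, deNovoHi = 1.5,
                                  deNovoLo = 1.1,
                                  deNovoScale = c("log2", "linear"),
                                  d0 = "estimate") {
    stopifnot(is(enrichment, "EnhancerEnrichment"))
    if (normalize && !isTRUE(metadata(enrichment)$normalized))
        enrichment <- quantileNormalize(enrichment)
    mat <- assay(enrichment, "enrichment")
    tbl <- moderatedTTest(mat, colData(enrichment)$condition, d0 = d0)
    tbl$q <- bhAdjust(tbl$p)
    tbl$class <- classifyDifferential(tbl, logfcThreshold, qThreshold,
                                      backgroundBand)
    tbl$class <- classifyDeNovo(tbl, deNovoHi, deNovoLo,
                                match.arg(deNovoScale))
    out <- granges(rowRanges(enrichment))
    mcols(out) <- DataFrame(tbl[, c("logFC", "t", "p", "q", "class",
                                    "meanCtrl", "meanTrt")])
    attr(out, "ebayes") <- list(d0 = attr(tbl, "d0"),
                                s0sq = attr(tbl, "s0sq"))
    out
}

#' Write a differential enhancer table as TSV
#'
#' Columns: chrom, start (0-based), end, logFC, t, p, q, class,
#' mean_ctrl_E, mean_trt_E.
#'
#' @param x GRanges from [differentialEnhancers()].
#' @param path output path.
#' @export
writeDifferentialTable <- function(x, path) {
    df <- data.frame(chrom = as.character(seqnames(x)),
                     start = GenomicRanges::start(x) - 1,
                     end = GenomicRanges::end(x),
                     logFC = mcols(x)$logFC, t = mcols(x)$t,
                     p = mcols(x)$p, q = mcols(x)$q,
                     class = mcols(x)$class,
                     mean_ctrl_E = mcols(x)$meanCtrl,
                     mean_trt_E = mcols(x)$meanTrt,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
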