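suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
    library(S4Vectors)
    library(SummarizedExperiment)
})

# terse GRanges constructor: 0-based half-open coordinates, as in BED
gr0 <- function(chrom, start, end) {
    GRanges(chrom, IRanges(start = start + 1, end = end))
}

# two-exon toy genes: exon1 = [tss, tss+1200), exon2 = [tss+3000, tss+4000)
makeGenes <- function(chrom, tss, ids = sprintf("g%03d", seq_along(tss))) {
    exons <- lapply(seq_along(tss), function(i) {
        GRanges(chrom[i], IRanges(start = c(tss[i] + 1, tss[i] + 3001),
                                  width = c(1200, 1000)), strand = "+")
    })
    names(exons) <- ids
    spans <- GRanges(chrom, IRanges(start = tss + 1, end = tss + 4000),
                     strand = "+")
    mcols(spans)$gene_id <- ids
    mcols(spans)$tss <- tss + 1
    mcols(spans)$gene_length <- 2200
    geneAnnotation(spans, exons)
}

# a fragment track with the given 0-based fragment starts on one chromosome
makeTrack <- function(starts, chrom = "chr1", width = 300,
                      librarySize = length(starts), id = "t", mark = "input",
                      condition = "control", replicate = 1, inputId = NA) {
    sampleTrack(id, mark, condition, replicate,
                fragments = GRanges(rep(chrom, length(starts)),
                                    IRanges(start = starts + 1,
                                            width = width)),
                librarySize = librarySize, inputId = inputId)
}

# ---- memoized synthetic-experiment analyses -------------------------------
# One full generator + pipeline run per seed, shared across test files; only
# small derived objects are retained so memory stays flat.
.analysisCache <- new.env(parent = emptyenv())

analyzedSim <- function(seed, ...) {
    key <- paste0("s", seed, "_", paste(deparse(list(...)), collapse = ""))
    key <- gsub("[^a-zA-Z0-9_]", "", key)
    if (!is.null(.analysisCache[[key]])) return(.analysisCache[[key]])
    cfg <- simConfig(seed = seed, includeBrd4 = FALSE, ...)
    dat <- simulateExperiment(cfg)
    marks <- vapply(dat$tracks, function(t) t@mark, character(1))
    ac <- lapply(dat$tracks[marks == "H3K27ac"], function(t) t@peaks)
    me1 <- lapply(dat$tracks[marks == "H3K4me1"], function(t) t@peaks)
    k4 <- mergeIntervals(do.call(c, unname(
        lapply(dat$tracks[marks == "H3K4me3"], function(t) t@peaks))))
    catalog <- filterRegulatory(callCandidateEnhancers(ac, me1),
                                dat$annotation, k4)
    enr <- computeEnrichment(catalog, dat$tracks)
    diffEnh <- differentialEnhancers(enr)
    rkC <- callSuperEnhancers(regions(catalog), dat$tracks, "control")
    rkT <- callSuperEnhancers(regions(catalog), dat$tracks, "treated")
    dse <- differentialSuperEnhancers(rkC, rkT, dat$tracks)
    # match called enhancers to planted truth by overlap
    tr <- dat$truth$enhancers
    trGr <- GRanges(tr$chrom, IRanges(tr$start + 1, tr$end))
    hits <- findOverlaps(diffEnh, trGr)
    direction <- rep(NA_character_, length(diffEnh))
    direction[queryHits(hits)] <- tr$direction[subjectHits(hits)]
    res <- list(truth = dat$truth, diffEnh = diffEnh,
                plantedDirection = direction, catalog = catalog,
                rankings = list(control = rkC, treated = rkT), diffSE = dse,
                annotation = dat$annotation, expression = dat$expression,
                lncrnas = dat$lncrnas, layout = dat$layout)
    .analysisCache[[key]] <- res
    res
}

# recovery of planted up/down direction from the differential classes
recoveryStats <- function(a) {
    cls <- mcols(a$diffEnh)$class
    dir <- a$plantedDirection
    calledUp <- cls %in% c("up", "de_novo_gained")
    calledDown <- cls %in% c("down", "de_novo_lost")
    nTrue <- sum(dir %in% c("up", "down"), na.rm = TRUE)
    tp <- sum(calledUp & dir == "up", na.rm = TRUE) +
        sum(calledDown & dir == "down", na.rm = TRUE)
    called <- sum(calledUp | calledDown)
    list(sensitivity = tp / nTrue,
         fdr = if (called == 0) 0 else (called - tp) / called)
}
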