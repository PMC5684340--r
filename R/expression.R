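#' TMM normalization factors
#'
#' Trimmed mean of M-values: for each sample against a reference column,
#' gene-wise log ratios (M) are trimmed by 30 percent on both sides and
#' gene-wise mean log intensities (A) by 5 percent, the surviving M values
#' are averaged with inverse-asymptotic-variance weights and exponentiated,
#' and the factors are centred so they multiply to one. The reference
#' column is the sample whose 75th-percentile count fraction is closest to
#' the mean across samples.
#'
#' @param counts numeric matrix, genes x samples.
#' @param refColumn optional reference column index.
#' @param logratioTrim,sumTrim trim fractions for M and A (defaults 0.3,
#'   0.05).
#' @return numeric vector of normalization factors, one per sample.
#' @export
tmmFactors <- function(counts, refColumn = NULL, logratioTrim = 0.3,
                       sumTrim = 0.05) {
    counts <- as.matrix(counts)
    if (ncol(counts) < 2) stop("need at least 2 samples")
    if (any(colSums(counts) == 0)) stop("all-zero sample column")
    lib <- colSums(counts)
    f75 <- vapply(seq_len(ncol(counts)), function(j)
        stats::quantile(counts[, j], 0.75) / lib[j], numeric(1))
    if (is.null(refColumn))
        refColumn <- which.min(abs(f75 - mean(f75)))
    f <- vapply(seq_len(ncol(counts)), function(j) {
        if (j == refColumn) return(1)
        .tmmPair(counts[, j], counts[, refColumn], lib[j], lib[refColumn],
                 logratioTrim, sumTrim)
    }, numeric(1))
    # centre so factors multiply to one
    f / exp(mean(log(f)))
}

.tmmPair <- function(obs, ref, nO, nR, logratioTrim, sumTrim) {
    M <- log2((obs / nO) / (ref / nR))
    A <- (log2(obs / nO) + log2(ref / nR)) / 2
    # asymptotic variance of M under binomial sampling; weights are 1/v
    v <- (nO - obs) / (nO * obs) + (nR - ref) / (nR * ref)
    fin <- is.finite(M) & is.finite(A) & A > -1e10
    M <- M[fin]; A <- A[fin]; v <- v[fin]
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loL <- floor(n * logratioTrim) + 1
    hiL <- n + 1 - loL
    loS <- floor(n * sumTrim) + 1
    hiS <- n + 1 - loS
    keep <- rank(M) >= loL & rank(M) <= hiL &
        rank(A) >= loS & rank(A) <= hiS
    fval <- sum(M[keep] / v[keep], na.rm = TRUE) /
        sum(1 / v[keep], na.rm = TRUE)
    if (!is.finite(fval)) fval <- 0
    2^fval
}

#' Normalized expression in arbitrary units
#'
#' TMM-scaled counts per million: counts divided by the TMM-effective
#' library size (library size times normalization factor), times one
#' million. This is the "A.U." scale on which the 100 A.U. expression
#' floor operates.
#'
#' @param counts matrix or data.frame of counts, genes x samples.
#' @return matrix of normalized expression values (A.U.).
#' @export
normalizedExpression <- function(counts) {
    counts <- as.matrix(counts)
    f <- tmmFactors(counts)
    sweep(counts, 2, colSums(counts) * f, "/") * 1e6
}

#' Transcripts per million
#'
#' @param counts numeric vector or matrix of counts (genes x samples).
#' @param geneLengths gene lengths in bp (> 0).
#' @return TPM values; each column sums to 1e6.
#' @export
tpm <- function(counts, geneLengths) {
    if (any(geneLengths <= 0)) stop("gene lengths must be positive")
    counts <- as.matrix(counts)
    rate <- counts / geneLengths
    tot <- colSums(rate)
    if (any(tot == 0)) stop("zero total count: TPM undefined")
    sweep(rate, 2, tot, "/") * 1e6
}

#' Call differentially expressed genes
#'
#' A gene is DE when its normalized coverage is at least `minCoverage` in
#' either condition and the linear fold change between the two conditions
#' (in either direction) is at least `minFc`.
#'
#' @param auCtrl,auTrt normalized expression per gene in the two
#'   conditions.
#' @param minCoverage coverage floor (default 10).
#' @param minFc fold-change threshold (default 1.5).
#' @return data.frame with columns de (logical), direction ("up", "down",
#'   "none") and log2fc (with a pseudocount of 1 unit).
#' @export
callDeGenes <- function(auCtrl, auTrt, minCoverage = 10, minFc = 1.5) {
    stopifnot(length(auCtrl) == length(auTrt))
    fcUp <- ifelse(auCtrl == 0, ifelse(auTrt == 0, 1, Inf), auTrt / auCtrl)
    fc <- pmax(fcUp, 1 / fcUp)
    de <- (auCtrl >= minCoverage | auTrt >= minCoverage) & fc >= minFc
    direction <- ifelse(!de, "none", ifelse(auTrt > auCtrl, "up", "down"))
    data.frame(de = de, direction = direction,
               log2fc = log2((auTrt + 1) / (auCtrl + 1)))
}

#' Assign enhancers to genes within a TSS window
#'
#' Links every (enhancer, gene) pair whose TSS lies within `window` bp of
#' the enhancer boundaries; a gene may link to many enhancers and vice
#' versa.
#'
#' @param enhancers GRanges.
#' @param annotation a [GeneAnnotation-class].
#' @param window flank in bp (default 250000).
#' @return data.frame with columns enhancer (index into `enhancers`),
#'   gene_id and distance (bp from the nearest enhancer edge to the TSS; 0
#'   when the TSS is inside the enhancer).
#' @export
assignEnhancersToGenes <- function(enhancers, annotation,
                                   window = 250000) {
    g <- regions(annotation)
    tssGr <- GRanges(seqnames(g), IRanges(start = mcols(g)$tss, width = 1))
    flanked <- GRanges(seqnames(enhancers),
                       IRanges(start = pmax(1, GenomicRanges::start(enhancers)
                                            - window),
                               end = GenomicRanges::end(enhancers) + window))
    hits <- findOverlaps(flanked, tssGr, ignore.strand = TRUE)
    ei <- queryHits(hits)
    gi <- subjectHits(hits)
    tss <- mcols(g)$tss[gi]
    dist <- pmax(0, pmax(GenomicRanges::start(enhancers)[ei] - tss,
                         tss - GenomicRanges::end(enhancers)[ei]))
    data.frame(enhancer = ei, gene_id = mcols(g)$gene_id[gi],
               distance = dist, stringsAsFactors = FALSE)
}

#' Map super-enhancers and typical enhancers to nearest expressed genes
#'
#' ROSE-geneMapper-style assignment: each region maps to the single
#' closest expressed gene whose TSS is within `window` bp of the region
#' centre. Genes below the expression floor in both conditions are
#' ignored; a gene claimed by both an SE and a TE is assigned to the SE;
#' expressed genes mapped by no region are labelled `no_enhancer`. Ties in
#' distance break to the lexicographically lower gene_id.
#'
#' @param ses,tes GRanges of super-enhancers and typical enhancers.
#' @param annotation a [GeneAnnotation-class].
#' @param auCtrl,auTrt named (by gene_id) normalized expression vectors.
#' @param window centre-to-TSS distance bound (default 50000).
#' @param auFloor expression floor in A.U. (default 100); a gene is
#'   expressed when at least one condition reaches it.
#' @return list with `regions` (data.frame: region_type, region, gene_id,
#'   distance for each mapped region) and `genes` (data.frame: gene_id,
#'   link_type in {SE, TE, no_enhancer}, region index).
#' @export
mapNearestGenesRose <- function(ses, tes, annotation, auCtrl, auTrt,
                                window = 50000, auFloor = 100) {
    g <- regions(annotation)
    ids <- mcols(g)$gene_id
    expressed <- pmax(auCtrl[ids], auTrt[ids]) >= auFloor
    gE <- g[expressed]
    idsE <- ids[expressed]
    tssE <- mcols(gE)$tss
    chromE <- as.character(seqnames(gE))
    mapOne <- function(reg, type) {
        if (length(reg) == 0)
            return(data.frame(region_type = character(0), region = integer(0),
                              gene_id = character(0), distance = numeric(0)))
        ctr <- floor((GenomicRanges::start(reg) +
                          GenomicRanges::end(reg)) / 2)
        chromR <- as.character(seqnames(reg))
        rows <- lapply(seq_along(reg), function(i) {
            ok <- chromE == chromR[i]
            d <- abs(tssE - ctr[i])
            ok <- ok & d <= window
            if (!any(ok)) return(NULL)
            cand <- which(ok)
            # nearest; distance ties break to lower gene_id
            cand <- cand[order(d[cand], idsE[cand])]
            data.frame(region_type = type, region = i,
                       gene_id = idsE[cand[1]], distance = d[cand[1]],
                       stringsAsFactors = FALSE)
        })
        do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    }
    seMap <- mapOne(ses, "SE")
    teMap <- mapOne(tes, "TE")
    regionsDf <- rbind(seMap, teMap)
    seGenes <- unique(seMap$gene_id)
    teGenes <- setdiff(unique(teMap$gene_id), seGenes)  # SE overrides TE
    linked <- c(seGenes, teGenes)
    noEnh <- setdiff(idsE, linked)
    genesDf <- rbind(
        if (length(seGenes)) data.frame(gene_id = seGenes,
                                        link_type = "SE",
                                        stringsAsFactors = FALSE),
        if (length(teGenes)) data.frame(gene_id = teGenes,
                                        link_type = "TE",
                                        stringsAsFactors = FALSE),
        if (length(noEnh)) data.frame(gene_id = noEnh,
                                      link_type = "no_enhancer",
                                      stringsAsFactors = FALSE))
    list(regions = regionsDf, genes = genesDf)
}

#' Cumulative expression-contribution summary for SE-associated genes
#'
#' Totals the normalized expression of SE-associated genes per condition,
#' reports the percent change after treatment, and splits that change into
#' percentage-point contributions per SE class (gained, lost, unchanged),
#' which sum exactly to the total. Also counts up/down-regulated
#' SE-associated genes at |log2 fc| > 1.
#'
#' @param geneClasses named character vector: SE class per SE-associated
#'   gene_id.
#' @param auCtrl,auTrt named normalized expression vectors.
#' @return list with totals, percentChange, classContribution (percentage
#'   points per class), nUp and nDown.
#' @export
contributionSummary <- function(geneClasses, auCtrl, auTrt) {
    ids <- names(geneClasses)
    totC <- sum(auCtrl[ids])
    totT <- sum(auTrt[ids])
    if (totC == 0) stop("zero control total: percent change undefined")
    pct <- 100 * (totT - totC) / totC
    contrib <- vapply(sort(unique(geneClasses)), function(k) {
        i <- ids[geneClasses == k]
        100 * (sum(auTrt[i]) - sum(auCtrl[i])) / totC
    }, numeric(1))
    lfc <- log2((auTrt[ids] + 1) / (auCtrl[ids] + 1))
    list(totalCtrl = totC, totalTrt = totT, percentChange = pct,
         classContribution = contrib,
         nUp = sum(lfc > 1), nDown = sum(lfc < -1))
}

#' Correlation of region activity change with nearest-gene expression
#'
#' For each differential region, finds the first, second and third nearest
#' expressed genes by centre-to-TSS distance and computes, per rank, the
#' Spearman correlation between the region's signal log2 fold change and
#' the genes' expression log2 fold change.
#'
#' @param diffRegions GRanges with a numeric metadata column `fc` (linear
#'   signal fold change, as from [differentialSuperEnhancers()]).
#' @param annotation a [GeneAnnotation-class].
#' @param auCtrl,auTrt named normalized expression vectors.
#' @param ranks nearest-gene ranks to evaluate (default 1:3).
#' @param auFloor expression floor in A.U. (default 100).
#' @return named numeric vector of Spearman correlations, one per rank
#'   (NA when fewer than 3 regions have a gene at that rank).
#' @export
nearestRankCorrelation <- function(diffRegions, annotation, auCtrl, auTrt,
                                   ranks = 1:3, auFloor = 100) {
    g <- regions(annotation)
    ids <- mcols(g)$gene_id
    expressed <- pmax(auCtrl[ids], auTrt[ids]) >= auFloor
    gE <- g[expressed]
    idsE <- ids[expressed]
    tssE <- mcols(gE)$tss
    chromE <- as.character(seqnames(gE))
    ctr <- floor((GenomicRanges::start(diffRegions) +
                      GenomicRanges::end(diffRegions)) / 2)
    chromR <- as.character(seqnames(diffRegions))
    regionLfc <- log2(mcols(diffRegions)$fc)
    exprLfc <- stats::setNames(log2((auTrt[idsE] + 1) / (auCtrl[idsE] + 1)),
                               idsE)
    vapply(ranks, function(r) {
        pair <- vapply(seq_along(diffRegions), function(i) {
            d <- abs(tssE - ctr[i])
            d[chromE != chromR[i]] <- Inf
            o <- order(d, idsE)
            if (length(o) < r || !is.finite(d[o[r]])) return(NA_real_)
            exprLfc[idsE[o[r]]]
        }, numeric(1))
        ok <- !is.na(pair)
        if (sum(ok) < 3) return(NA_real_)
        stats::cor(regionLfc[ok], pair[ok], method = "spearman")
    }, numeric(1)) |> stats::setNames(paste0("rank", ranks))
}
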