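#' Stitch enhancers into candidate super-enhancer regions
#'
#' Joins enhancers whose end-to-start distance is at most `gap` bp (12.5 kb
#' by default) into single stitched regions: two enhancers share a region
#' iff they are connected by a chain of neighbours each within the gap.
#' Output regions are separated by more than `gap` and the union of
#' constituent bases is preserved within each span.
#'
#' @param enhancers GRanges of enhancers.
#' @param gap maximal stitching distance in bp (default 12500).
#' @return GRanges of stitched spans with metadata columns `nConstituents`
#'   and `revmap` (indices of constituents in the input).
#' @export
stitchEnhancers <- function(enhancers, gap = 12500) {
    if (length(enhancers) == 0) return(GRanges())
    st <- reduce(sort(GRanges(seqnames(enhancers),
                              IRanges::ranges(enhancers))),
                 min.gapwidth = gap + 1, with.revmap = TRUE)
    ord <- GenomicRanges::order(GRanges(seqnames(enhancers),
                                        IRanges::ranges(enhancers)))
    mcols(st)$revmap <- S4Vectors::endoapply(
        mcols(st)$revmap, function(i) ord[i])
    mcols(st)$nConstituents <- lengths(mcols(st)$revmap)
    st
}

#' Background-subtracted per-million signal over regions
#'
#' rpm over each region in the ChIP tracks minus rpm in the matched input
#' tracks, floored at zero. Replicates are averaged after per-million
#' scaling. When no input tracks are supplied the ChIP rpm is returned
#' with a warning.
#'
#' @param x GRanges of regions (e.g. stitched spans).
#' @param chipTracks list of [SampleTrack-class] ChIP replicates.
#' @param inputTracks list of matched input tracks, or NULL.
#' @return numeric vector of signals (rpm), one per region.
#' @export
backgroundSubtractedSignal <- function(x, chipTracks, inputTracks = NULL) {
    stopifnot(length(chipTracks) >= 1)
    rpm <- function(tracks) {
        m <- vapply(tracks, function(t) scaledRegionCounts(x, t),
                    numeric(length(x)))
        rowMeans(matrix(m, nrow = length(x)))
    }
    chip <- rpm(chipTracks)
    if (is.null(inputTracks) || length(inputTracks) == 0) {
        warning("no input tracks: returning unsubtracted ChIP signal")
        return(chip)
    }
    pmax(0, chip - rpm(inputTracks))
}

#' Rank-curve super-enhancer cutoff
#'
#' Sorts signals ascending, scales rank and signal to the unit square and
#' finds the tangency point of a slope-one line with the curve: the index
#' maximizing (x - y), ties broken to the last (highest-signal) index.
#' Regions with signal strictly above the cutoff signal are
#' super-enhancers. A flat signal vector yields zero SEs.
#'
#' @param signals non-negative numeric vector (length >= 2).
#' @return list with `cutoffSignal`, `isSE` (logical, input order),
#'   `order` (ascending permutation) and `cutoffIndex` (in sorted order).
#' @export
roseCutoff <- function(signals) {
    n <- length(signals)
    if (n < 2) stop("need at least 2 regions to place a cutoff")
    if (any(signals < 0)) stop("signals must be non-negative")
    o <- order(signals)
    s <- signals[o]
    if (s[n] == s[1]) {
        message("flat signal vector: no super-enhancers called")
        return(list(cutoffSignal = s[n], isSE = rep(FALSE, n), order = o,
                    cutoffIndex = n))
    }
    xs <- (seq_len(n) - 1) / (n - 1)
    ys <- (s - s[1]) / (s[n] - s[1])
    d <- xs - ys
    idx <- max(which(d == max(d)))
    cutoff <- s[idx]
    list(cutoffSignal = cutoff, isSE = signals > cutoff, order = o,
         cutoffIndex = idx)
}

#' Call super-enhancers for one condition
#'
#' Composition of [stitchEnhancers()], [backgroundSubtractedSignal()] and
#' [roseCutoff()]: stitches the enhancer set, computes the H3K27ac (or
#' other mark) background-subtracted signal per stitched region using the
#' condition's ChIP replicates and their matched inputs, and splits the
#' ranking at the tangency cutoff.
#'
#' @param enhancers GRanges of enhancers (the H3K27ac catalog, or BRD4
#'   peaks for BRD4 mode).
#' @param tracks named list of [SampleTrack-class] containing the mark's
#'   ChIP samples and their inputs.
#' @param condition "control" or "treated".
#' @param mark ChIP mark supplying the signal (default "H3K27ac").
#' @param gap stitching distance (default 12500).
#' @return A [RoseRanking-class].
#' @export
callSuperEnhancers <- function(enhancers, tracks, condition,
                               mark = "H3K27ac", gap = 12500) {
    if (length(enhancers) == 0)
        return(new("RoseRanking", regions = GRanges(),
                   cutoffSignal = NA_real_, condition = condition))
    st <- stitchEnhancers(enhancers, gap = gap)
    sel <- selectChipInputs(tracks, mark, condition)
    sig <- backgroundSubtractedSignal(st, sel$chip, sel$input)
    if (length(st) == 1) {
        mcols(st)$signal <- sig
        mcols(st)$rank <- 1L
        mcols(st)$isSE <- FALSE
        return(new("RoseRanking", regions = st, cutoffSignal = sig,
                   condition = condition))
    }
    rc <- roseCutoff(sig)
    st <- st[rc$order]
    mcols(st)$signal <- sig[rc$order]
    mcols(st)$rank <- seq_along(st)
    mcols(st)$isSE <- rc$isSE[rc$order]
    new("RoseRanking", regions = st, cutoffSignal = rc$cutoffSignal,
        condition = condition)
}

selectChipInputs <- function(tracks, mark, condition) {
    chip <- Filter(function(t) t@mark == mark && t@condition == condition,
                   tracks)
    if (length(chip) == 0)
        stop(sprintf("no %s tracks for condition '%s'", mark, condition))
    ids <- vapply(tracks, function(t) t@sampleId, character(1))
    input <- list()
    for (t in chip)
        if (!is.na(t@inputId) && t@inputId %in% ids)
            input[[t@inputId]] <- tracks[[which(ids == t@inputId)[1]]]
    list(chip = chip, input = unname(input))
}

#' Differential (gained/lost) super-enhancers
#'
#' Evaluates every region that is a super-enhancer in at least one
#' condition: SE spans from the two rankings are merged where they overlap
#' so each locus is classified once, background-subtracted signal is
#' recomputed on the merged spans for both conditions, and the fold change
#' `(signal_trt + eps) / (signal_ctrl + eps)` classifies each region as
#' gained (fc >= `gainedFc`), lost (fc <= `lostFc`) or unchanged.
#'
#' @param ctrl,trt [RoseRanking-class] for the two conditions.
#' @param tracks named list of [SampleTrack-class] with the mark's ChIP and
#'   input samples for both conditions.
#' @param mark signal mark (default "H3K27ac").
#' @param epsilon pseudo-signal in rpm guarding the ratio (default 0.1).
#' @param gainedFc,lostFc fold-change thresholds (defaults 2 and 0.5).
#' @return GRanges of evaluated spans with metadata columns signalCtrl,
#'   signalTrt, fc, class.
#' @export
differentialSuperEnhancers <- function(ctrl, trt, tracks,
                                       mark = "H3K27ac", epsilon = 0.1,
                                       gainedFc = 2, lostFc = 0.5) {
    stopifnot(is(ctrl, "RoseRanking"), is(trt, "RoseRanking"))
    univ <- reduce(sort(c(granges(regions(ctrl)[isSE(ctrl)]),
                          granges(regions(trt)[isSE(trt)]))),
                   min.gapwidth = 1L)
    if (length(univ) == 0) return(GRanges())
    sc <- selectChipInputs(tracks, mark, "control")
    st <- selectChipInputs(tracks, mark, "treated")
    sigC <- backgroundSubtractedSignal(univ, sc$chip, sc$input)
    sigT <- backgroundSubtractedSignal(univ, st$chip, st$input)
    fc <- (sigT + epsilon) / (sigC + epsilon)
    cls <- ifelse(fc >= gainedFc, "gained",
                  ifelse(fc <= lostFc, "lost", "unchanged"))
    mcols(univ)$signalCtrl <- sigC
    mcols(univ)$signalTrt <- sigT
    mcols(univ)$fc <- fc
    mcols(univ)$class <- cls
    univ
}

#' Per-class summary statistics for differential super-enhancers
#'
#' Median length (kb), median background-subtracted signal (rpm) and
#' median signal density (rpm/bp) per class, for both conditions.
#'
#' @param diffSE GRanges from [differentialSuperEnhancers()].
#' @return data.frame, one row per class present.
#' @export
seClassSummary <- function(diffSE) {
    cls <- mcols(diffSE)$class
    w <- GenomicRanges::width(diffSE)
    do.call(rbind, lapply(sort(unique(cls)), function(k) {
        i <- cls == k
        data.frame(class = k, n = sum(i),
                   median_length_kb = stats::median(w[i]) / 1000,
                   median_signal_ctrl_rpm =
                       stats::median(mcols(diffSE)$signalCtrl[i]),
                   median_signal_trt_rpm =
                       stats::median(mcols(diffSE)$signalTrt[i]),
                   median_density_ctrl_rpm_bp =
                       stats::median(mcols(diffSE)$signalCtrl[i] / w[i]),
                   median_density_trt_rpm_bp =
                       stats::median(mcols(diffSE)$signalTrt[i] / w[i]),
                   stringsAsFactors = FALSE)
    }))
}
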