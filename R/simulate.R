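#' Simulation configuration
#'
#' Builds the configuration for the synthetic experiment generator. The
#' defaults emulate the study design the analysis assumes: two conditions x
#' two replicates of H3K27ac/H3K4me1/BRD4 ChIP with matched inputs, a few
#' hundred enhancers of which fixed fractions are planted as up, down,
#' unaffected, de novo gained or de novo lost, clusters of enhancers dense
#' enough to stitch into super-enhancers, an expression table whose fold
#' changes follow the planted enhancer classes, and lncRNAs of which a
#' fraction overlap enhancers.
#'
#' @param seed integer RNG seed; fixed seed gives bit-identical output.
#' @param chromLengths named vector of chromosome lengths (default two 50 Mb
#'   chromosomes: large enough for 250 kb assignment windows and 12.5 kb
#'   stitching without edge effects, small enough for seconds-scale runs).
#' @param nGenes total genes, including distal "no enhancer" genes.
#' @param nEnhancers total planted enhancers (cluster constituents included).
#' @param classFractions named fractions (up, down, unaffected,
#'   de_novo_gained, de_novo_lost) applied to non-cluster enhancers; must
#'   sum to 1.
#' @param nSeClusters,enhancersPerCluster planted super-enhancer clusters;
#'   constituents are spaced < 12.5 kb apart.
#' @param effectSize planted log2 enrichment difference for up/down classes.
#' @param backgroundRate expected background fragments per reference-length
#'   (2 kb) region; also the input-track rate.
#' @param signalRate expected extra ChIP fragments at a baseline enhancer;
#'   baseline log2 enrichment is log2(1 + signalRate/backgroundRate).
#' @param countNoise "poisson" or "negative_binomial" for planted signal and
#'   expression counts.
#' @param nbDispersion negative-binomial dispersion when used.
#' @param exprEffect planted expression log2 fold change for genes linked to
#'   up/down enhancers (default 1, i.e. linear fold 2 >= the 1.5 DE rule).
#' @param nLncrnas,lncrnaOverlapFraction lncRNA count and the fraction
#'   planted to overlap an enhancer.
#' @param enhancerLengthRange,lncrnaLengthRange uniform length ranges in bp.
#' @param seSignalMult ChIP signal multiplier for cluster constituents
#'   (default 10, so planted clusters dominate the signal ranking).
#' @param seClassFractions fractions of clusters planted gained, lost,
#'   unchanged.
#' @param seGainRatio treated/control signal ratio for gained clusters (and
#'   its inverse for lost ones).
#' @param fragmentLength simulated fragment span in bp.
#' @param nSpuriousPeaks single-sample peaks with no planted signal.
#' @param nDecoys candidate regions placed over promoters, exons and
#'   H3K4me3 peaks, to exercise the regulatory-region filters.
#' @param includeBrd4 also generate BRD4 tracks (peaks + fragments).
#' @param peakJitter per-sample peak boundary jitter in bp.
#' @return A list of class `simConfig`.
#' @export
simConfig <- function(seed = 1,
                      chromLengths = c(chr1 = 5e7, chr2 = 5e7),
                      nGenes = 600,
                      nEnhancers = 500,
                      classFractions = c(up = 0.15, down = 0.15,
                                         unaffected = 0.5,
                                         de_novo_gained = 0.1,
                                         de_novo_lost = 0.1),
                      nSeClusters = 9,
                      enhancersPerCluster = 5,
                      effectSize = 2,
                      backgroundRate = 20,
                      signalRate = 60,
                      countNoise = c("poisson", "negative_binomial"),
                      nbDispersion = 0.1,
                      exprEffect = 1,
                      nLncrnas = 60,
                      lncrnaOverlapFraction = 0.3,
                      enhancerLengthRange = c(1000, 3000),
                      lncrnaLengthRange = c(500, 5000),
                      seSignalMult = 10,
                      seClassFractions = c(gained = 1/3, lost = 1/3,
                                           unchanged = 1/3),
                      seGainRatio = 4,
                      fragmentLength = 300,
                      nSpuriousPeaks = 60,
                      nDecoys = 24,
                      includeBrd4 = TRUE,
                      peakJitter = 200) {
    countNoise <- match.arg(countNoise)
    stopifnot(abs(sum(classFractions) - 1) < 1e-8,
              abs(sum(seClassFractions) - 1) < 1e-8,
              backgroundRate > 0, signalRate > 0,
              nSeClusters * enhancersPerCluster <= nEnhancers ||
                  nEnhancers == 0)
    cfg <- list(seed = seed, chromLengths = chromLengths, nGenes = nGenes,
                nEnhancers = nEnhancers, classFractions = classFractions,
                nSeClusters = nSeClusters,
                enhancersPerCluster = enhancersPerCluster,
                effectSize = effectSize, backgroundRate = backgroundRate,
                signalRate = signalRate, countNoise = countNoise,
                nbDispersion = nbDispersion, exprEffect = exprEffect,
                nLncrnas = nLncrnas,
                lncrnaOverlapFraction = lncrnaOverlapFraction,
                enhancerLengthRange = enhancerLengthRange,
                lncrnaLengthRange = lncrnaLengthRange,
                seSignalMult = seSignalMult,
                seClassFractions = seClassFractions,
                seGainRatio = seGainRatio,
                fragmentLength = fragmentLength,
                nSpuriousPeaks = nSpuriousPeaks, nDecoys = nDecoys,
                includeBrd4 = includeBrd4, peakJitter = peakJitter)
    class(cfg) <- "simConfig"
    cfg
}

# draw counts under the configured noise model
.simCounts <- function(n, mu, cfg) {
    if (cfg$countNoise == "poisson") stats::rpois(n, mu)
    else stats::rnbinom(n, size = 1 / cfg$nbDispersion, mu = mu)
}

# integer counts per class honouring fractions up to rounding
.roundedCounts <- function(n, fractions) {
    cs <- round(cumsum(fractions) * n)
    counts <- diff(c(0, cs))
    names(counts) <- names(fractions)
    counts
}

#' Simulate a full synthetic ChIP-seq / RNA-seq experiment
#'
#' Generates sample tracks (peaks + fragment placements), gene annotation,
#' an expression count table, lncRNA loci and a truth table, all seeded and
#' reproducible. See [simConfig()] for the planted structure.
#'
#' Planted "up" enhancers have treated log2 enrichment exceeding control by
#' `effectSize`; de novo gained ones have control enrichment below 1.1 and
#' treated above 1.5. Cluster constituents sit within 12.5 kb of their
#' neighbours and carry a signal multiplier so they stitch into
#' super-enhancers; gained/lost clusters change signal by `seGainRatio`.
#' Every planted enhancer is covered by peaks in both replicates of each
#' condition in which it is active, and spurious single-sample peaks plus
#' promoter/exon/H3K4me3 decoys are added to exercise the support and
#' exclusion filters.
#'
#' @param config a [simConfig()] list.
#' @return A list with elements `tracks` (named list of
#'   [SampleTrack-class]), `annotation` ([GeneAnnotation-class]),
#'   `expression` (data.frame gene_id, length, count_ctrl, count_trt),
#'   `lncrnas` (GRanges), `truth` (list of data.frames: enhancers, clusters,
#'   genes, lncrnas), `layout` (Seqinfo) and `config`.
#' @export
simulateExperiment <- function(config = simConfig()) {
    stopifnot(inherits(config, "simConfig"))
    withSeed(config$seed, .simulateExperiment(config))
}

.simulateExperiment <- function(cfg) {
    layout <- genomeLayout(cfg$chromLengths)
    chroms <- seqlevels(layout)
    chromLen <- as.numeric(seqlengths(layout))
    fixSeq <- function(gr) {
        GenomeInfoDb::seqlevels(gr) <- chroms
        GenomeInfoDb::seqinfo(gr) <- layout
        gr
    }
    refLen <- mean(cfg$enhancerLengthRange)
    baseE <- log2(1 + cfg$signalRate / cfg$backgroundRate)
    deNovoLowE <- 0.8

    ## ---- enhancer placement -------------------------------------------
    nClu <- if (cfg$nEnhancers > 0) cfg$nSeClusters else 0L
    perClu <- cfg$enhancersPerCluster
    nSing <- cfg$nEnhancers - nClu * perClu
    singClasses <- rep(names(cfg$classFractions),
                       .roundedCounts(nSing, cfg$classFractions))
    if (nSing > 0) singClasses <- sample(singClasses)
    cluClasses <- rep(names(cfg$seClassFractions),
                      .roundedCounts(nClu, cfg$seClassFractions))

    usableEnd <- 0.72 * chromLen   # reserve chromosome tails
    chromIdx <- 1L
    cursor <- 1e5
    enh <- list()     # per-enhancer rows
    clu <- list()
    geneSpots <- list()  # linked-gene TSS positions
    eid <- 0L
    placeAdvance <- function(width) {
        # move to a chromosome that can hold `width`; error when none can
        repeat {
            if (chromIdx > length(chroms))
                stop("genome too small to place requested elements ",
                     "without violating spacing")
            if (cursor + width <= usableEnd[chromIdx]) break
            chromIdx <<- chromIdx + 1L
            cursor <<- 1e5
        }
    }
    lenDraw <- function(n) round(stats::runif(n, cfg$enhancerLengthRange[1],
                                              cfg$enhancerLengthRange[2]))
    for (k in seq_len(nClu)) {
        lens <- lenDraw(perClu)
        gaps <- round(stats::runif(perClu - 1, 2000, 8000))
        width <- sum(lens) + sum(gaps)
        gap0 <- round(stats::runif(1, 40000, 70000))
        placeAdvance(gap0 + width + 45000)
        cursor <- cursor + gap0
        s <- cursor + c(0, cumsum(lens[-perClu] + gaps))
        e <- s + lens
        cls <- cluClasses[k]
        for (j in seq_len(perClu)) {
            eid <- eid + 1L
            enh[[eid]] <- data.frame(
                enhancer_id = eid, chrom = chroms[chromIdx],
                start = s[j], end = e[j],
                class = switch(cls, gained = "up", lost = "down",
                               unchanged = "unaffected"),
                cluster_id = k, cluster_class = cls,
                stringsAsFactors = FALSE)
        }
        clu[[k]] <- data.frame(cluster_id = k, class = cls,
                               chrom = chroms[chromIdx],
                               span_start = s[1], span_end = e[perClu],
                               n_constituents = perClu,
                               stringsAsFactors = FALSE)
        geneSpots[[length(geneSpots) + 1L]] <- data.frame(
            chrom = chroms[chromIdx],
            tss = e[perClu] + round(stats::runif(1, 5000, 15000)),
            linked = eid, link_class = cls, stringsAsFactors = FALSE)
        cursor <- e[perClu]
    }
    for (j in seq_len(max(nSing, 0))) {
        len <- lenDraw(1)
        gap0 <- round(stats::runif(1, 40000, 70000))
        placeAdvance(gap0 + len + 45000)
        cursor <- cursor + gap0
        eid <- eid + 1L
        enh[[eid]] <- data.frame(
            enhancer_id = eid, chrom = chroms[chromIdx],
            start = cursor, end = cursor + len, class = singClasses[j],
            cluster_id = NA_integer_, cluster_class = NA_character_,
            stringsAsFactors = FALSE)
        geneSpots[[length(geneSpots) + 1L]] <- data.frame(
            chrom = chroms[chromIdx],
            tss = cursor + len + round(stats::runif(1, 5000, 30000)),
            linked = eid, link_class = singClasses[j],
            stringsAsFactors = FALSE)
        cursor <- cursor + len
    }
    enh <- if (length(enh)) do.call(rbind, enh) else
        data.frame(enhancer_id = integer(0), chrom = character(0),
                   start = numeric(0), end = numeric(0),
                   class = character(0), cluster_id = integer(0),
                   cluster_class = character(0))
    cluDf <- if (length(clu)) do.call(rbind, clu) else NULL

    ## planted per-condition ChIP rates (fragments per reference region)
    rateOf <- function(Ec) cfg$backgroundRate * 2^Ec
    Ectrl <- c(up = baseE, down = baseE + cfg$effectSize,
               unaffected = baseE, de_novo_gained = deNovoLowE,
               de_novo_lost = deNovoLowE + cfg$effectSize)
    Etrt <- c(up = baseE + cfg$effectSize, down = baseE,
              unaffected = baseE, de_novo_gained = deNovoLowE +
                  cfg$effectSize, de_novo_lost = deNovoLowE)
    if (nrow(enh) > 0) {
        enh$chipRateCtrl <- rateOf(Ectrl[enh$class])
        enh$chipRateTrt <- rateOf(Etrt[enh$class])
        isClu <- !is.na(enh$cluster_id)
        base <- rateOf(baseE) * cfg$seSignalMult
        enh$chipRateCtrl[isClu] <- ifelse(
            enh$cluster_class[isClu] == "lost", base * cfg$seGainRatio, base)
        enh$chipRateTrt[isClu] <- ifelse(
            enh$cluster_class[isClu] == "gained", base * cfg$seGainRatio,
            ifelse(enh$cluster_class[isClu] == "lost", base, base))
        enh$direction <- ifelse(
            enh$chipRateTrt > enh$chipRateCtrl, "up",
            ifelse(enh$chipRateTrt < enh$chipRateCtrl, "down", "none"))
    } else {
        enh$chipRateCtrl <- enh$chipRateTrt <- numeric(0)
        enh$direction <- character(0)
    }

    ## ---- genes ---------------------------------------------------------
    geneSpots <- if (length(geneSpots)) do.call(rbind, geneSpots) else NULL
    nLinked <- if (is.null(geneSpots)) 0L else nrow(geneSpots)
    nFar <- max(cfg$nGenes - nLinked, 0L)
    tailAlloc <- local({
        tcIdx <- 1L
        tc <- 0.75 * chromLen + 5e4
        tailEnd <- chromLen - 5e4
        function(width) {
            repeat {
                if (tcIdx > length(chroms))
                    stop("genome too small to place requested elements ",
                         "without violating spacing")
                if (tc[tcIdx] + width <= tailEnd[tcIdx]) break
                tcIdx <<- tcIdx + 1L
            }
            pos <- tc[tcIdx]
            tc[tcIdx] <<- tc[tcIdx] + width
            list(chrom = chroms[tcIdx], pos = pos)
        }
    })
    farSpots <- vector("list", nFar)
    for (j in seq_len(nFar)) {
        a <- tailAlloc(15000)
        farSpots[[j]] <- data.frame(chrom = a$chrom, tss = a$pos + 5000,
                                    linked = NA_integer_,
                                    link_class = "none",
                                    stringsAsFactors = FALSE)
    }
    spots <- rbind(geneSpots, if (nFar) do.call(rbind, farSpots))
    nG <- nrow(spots)
    geneIds <- sprintf("gene%04d", seq_len(nG))
    strand <- rep("+", nG)
    strand[is.na(spots$linked)][c(FALSE, TRUE)] <- "-"  # vary strand distally
    # exon structure: 1200 bp + 1000 bp exons, 1800 bp intron
    tss <- round(spots$tss)
    exS1 <- ifelse(strand == "+", tss, tss - 1199)
    exS2 <- ifelse(strand == "+", tss + 3000, tss - 3999)
    exonList <- lapply(seq_len(nG), function(i) {
        fixSeq(GRanges(spots$chrom[i],
                       IRanges(start = c(exS1[i], exS2[i]),
                               width = c(1200, 1000)), strand = strand[i]))
    })
    names(exonList) <- geneIds
    spans <- fixSeq(GRanges(spots$chrom,
                            IRanges(start = pmin(exS1, exS2),
                                    end = pmax(exS1 + 1199, exS2 + 999)),
                            strand = strand))
    mcols(spans)$gene_id <- geneIds
    mcols(spans)$tss <- tss
    mcols(spans)$gene_length <- 2200
    annotation <- geneAnnotation(spans, exonList)

    ## expression with planted fold changes
    lfc <- c(up = cfg$exprEffect, down = -cfg$exprEffect, unaffected = 0,
             de_novo_gained = cfg$exprEffect,
             de_novo_lost = -cfg$exprEffect, gained = cfg$exprEffect,
             lost = -cfg$exprEffect, unchanged = 0, none = 0)[
                 spots$link_class]
    mu <- 2^stats::rnorm(nG, mean = 8, sd = 2)
    linked <- !is.na(spots$linked)
    mu[linked] <- pmax(2^stats::rnorm(sum(linked), 8.5, 1), 40)
    countCtrl <- .simCounts(nG, mu, cfg)
    countTrt <- .simCounts(nG, mu * 2^lfc, cfg)
    expression <- data.frame(gene_id = geneIds, length = 2200,
                             count_ctrl = countCtrl, count_trt = countTrt,
                             stringsAsFactors = FALSE)

    ## ---- lncRNAs -------------------------------------------------------
    lnc <- .placeLncrnas(cfg, enh, layout)

    ## ---- peaks and fragments ------------------------------------------
    jit <- function(n) round(stats::runif(n, 0, cfg$peakJitter))
    enhGr <- fixSeq(if (nrow(enh)) GRanges(enh$chrom,
                                           IRanges(enh$start + 1, enh$end))
                    else GRanges())
    presentCtrl <- enh$chipRateCtrl >= 2 * cfg$backgroundRate
    presentTrt <- enh$chipRateTrt >= 2 * cfg$backgroundRate
    peakFor <- function(present) {
        if (!any(present)) return(GRanges())
        g <- enhGr[present]
        fixSeq(GRanges(seqnames(g),
                IRanges(start = pmax(1, GenomicRanges::start(g) -
                                         jit(length(g))),
                        end = GenomicRanges::end(g) + jit(length(g)))))
    }

    ## decoys: promoter / exon / H3K4me3 candidates that filters must drop
    nEach <- cfg$nDecoys %/% 3
    farIdx <- which(!linked)
    promDecoy <- exonDecoy <- k4Decoy <- fixSeq(GRanges())
    if (cfg$nEnhancers > 0 && nEach > 0 && length(farIdx) >= 2 * nEach) {
        pd <- farIdx[seq_len(nEach)]
        ed <- farIdx[nEach + seq_len(nEach)]
        promDecoy <- fixSeq(GRanges(spots$chrom[pd],
                                    IRanges(start = tss[pd] - 800,
                                            end = tss[pd] + 800)))
        exonDecoy <- fixSeq(GRanges(spots$chrom[ed],
                                    IRanges(start = exS2[ed] - 100,
                                            end = exS2[ed] + 1099)))
        k4 <- lapply(seq_len(nEach), function(i) tailAlloc(20000))
        k4Decoy <- fixSeq(GRanges(vapply(k4, `[[`, character(1), "chrom"),
                                  IRanges(start = vapply(k4, function(a)
                                      a$pos + 8000, numeric(1)),
                                      width = 1500)))
    }
    decoys <- c(promDecoy, exonDecoy, k4Decoy)

    ## spurious single-sample peaks, cycling over the four samples per mark
    spur <- if (cfg$nSpuriousPeaks > 0) {
        sp <- lapply(seq_len(cfg$nSpuriousPeaks), function(i) tailAlloc(8000))
        fixSeq(GRanges(vapply(sp, `[[`, character(1), "chrom"),
                       IRanges(start = vapply(sp, function(a) a$pos + 3000,
                                              numeric(1)), width = 1200)))
    } else fixSeq(GRanges())
    spurSample <- rep_len(1:4, length(spur))

    condOf <- c("control", "control", "treated", "treated")
    repOf <- c(1L, 2L, 1L, 2L)
    acPeaks <- me1Peaks <- brdPeaks <- vector("list", 4)
    for (s in 1:4) {
        present <- if (condOf[s] == "control") presentCtrl else presentTrt
        acPeaks[[s]] <- sort(c(peakFor(present), decoys,
                               spur[spurSample == s]))
        me1Peaks[[s]] <- sort(c(peakFor(rep(TRUE, nrow(enh))), decoys,
                                spur[spurSample == ((s %% 4) + 1)]))
        brdPeaks[[s]] <- sort(peakFor(present))
    }
    promAll <- promoterWindows(annotation, 750)
    k4me3Peaks <- sort(c(promAll, k4Decoy))

    ## fragments: uniform background + planted extras inside enhancers
    G <- totalLength(layout)
    density <- cfg$backgroundRate / refLen
    chromProb <- chromLen / G
    bgFragments <- function() {
        n <- stats::rpois(1, density * G)
        ci <- sample.int(length(chroms), n, replace = TRUE,
                         prob = chromProb)
        st <- floor(stats::runif(n, 1, chromLen[ci] - cfg$fragmentLength))
        fixSeq(GRanges(chroms[ci], IRanges(start = st,
                                           width = cfg$fragmentLength)))
    }
    extraFragments <- function(rates) {
        if (nrow(enh) == 0) return(fixSeq(GRanges()))
        lenFac <- (enh$end - enh$start) / refLen
        extra <- pmax(0, rates - cfg$backgroundRate) * lenFac
        k <- .simCounts(nrow(enh), extra, cfg)
        if (sum(k) == 0) return(GRanges())
        idx <- rep.int(seq_len(nrow(enh)), k)
        st <- floor(enh$start[idx] +
                    stats::runif(sum(k)) * (enh$end[idx] - enh$start[idx]))
        fixSeq(GRanges(enh$chrom[idx], IRanges(start = st + 1,
                                               width = cfg$fragmentLength)))
    }
    tracks <- list()
    for (s in 1:4) {
        cond <- condOf[s]; r <- repOf[s]
        rates <- if (cond == "control") enh$chipRateCtrl else enh$chipRateTrt
        inId <- sprintf("input_%s_%d", cond, r)
        frAc <- c(bgFragments(), extraFragments(rates))
        tracks[[sprintf("H3K27ac_%s_%d", cond, r)]] <- sampleTrack(
            sprintf("H3K27ac_%s_%d", cond, r), "H3K27ac", cond, r,
            peaks = acPeaks[[s]], fragments = frAc, inputId = inId)
        tracks[[sprintf("H3K4me1_%s_%d", cond, r)]] <- sampleTrack(
            sprintf("H3K4me1_%s_%d", cond, r), "H3K4me1", cond, r,
            peaks = me1Peaks[[s]], inputId = inId)
        if (cfg$includeBrd4) {
            frBrd <- c(bgFragments(), extraFragments(rates))
            tracks[[sprintf("BRD4_%s_%d", cond, r)]] <- sampleTrack(
                sprintf("BRD4_%s_%d", cond, r), "BRD4", cond, r,
                peaks = brdPeaks[[s]], fragments = frBrd, inputId = inId)
        }
        tracks[[inId]] <- sampleTrack(inId, "input", cond, r,
                                      fragments = bgFragments())
    }
    tracks[["H3K4me3_control_1"]] <- sampleTrack(
        "H3K4me3_control_1", "H3K4me3", "control", 1L, peaks = k4me3Peaks)
    tracks[["H3K4me3_treated_1"]] <- sampleTrack(
        "H3K4me3_treated_1", "H3K4me3", "treated", 1L, peaks = k4me3Peaks)

    truth <- list(
        enhancers = cbind(enh,
                          linked_gene = c(geneIds[match(enh$enhancer_id,
                                                        spots$linked)])),
        clusters = cluDf,
        genes = data.frame(gene_id = geneIds,
                           category = ifelse(linked, ifelse(
                               !is.na(spots$linked) &
                                   spots$link_class %in%
                                   c("gained", "lost", "unchanged"),
                               "cluster_linked", "enhancer_linked"), "far"),
                           linked_enhancer = spots$linked,
                           link_class = spots$link_class,
                           planted_lfc = unname(lfc), mu = mu,
                           stringsAsFactors = FALSE),
        lncrnas = lnc$truth)

    list(tracks = tracks, annotation = annotation, expression = expression,
         lncrnas = lnc$gr, truth = truth, layout = layout, config = cfg)
}

# place lncRNAs: a planted fraction centered on enhancers, the rest uniform
# with rejection against enhancer overlap
.placeLncrnas <- function(cfg, enh, layout) {
    n <- cfg$nLncrnas
    if (n == 0)
        return(list(gr = GRanges(),
                    truth = data.frame(lncrna_id = character(0),
                                       overlaps_enhancer = integer(0))))
    chroms <- seqlevels(layout)
    chromLen <- as.numeric(seqlengths(layout))
    lens <- round(stats::runif(n, cfg$lncrnaLengthRange[1],
                               cfg$lncrnaLengthRange[2]))
    nOv <- min(round(cfg$lncrnaOverlapFraction * n), nrow(enh))
    chrom <- character(n); st <- numeric(n)
    ovEnh <- rep(NA_integer_, n)
    if (nOv > 0) {
        pick <- sample.int(nrow(enh), nOv)
        ovEnh[seq_len(nOv)] <- pick
        chrom[seq_len(nOv)] <- enh$chrom[pick]
        lo <- enh$start[pick] - lens[seq_len(nOv)] + 50
        hi <- enh$end[pick] - 50
        st[seq_len(nOv)] <- floor(stats::runif(nOv, pmax(1, lo), hi))
    }
    rest <- setdiff(seq_len(n), seq_len(nOv))
    if (length(rest) > 0) {
        enhGr <- if (nrow(enh)) GRanges(enh$chrom,
                                        IRanges(enh$start + 1, enh$end))
                 else GRanges()
        GenomeInfoDb::seqlevels(enhGr) <- chroms
        todo <- rest
        for (iter in 1:100) {
            if (length(todo) == 0) break
            ci <- sample.int(length(chroms), length(todo), replace = TRUE,
                             prob = chromLen / sum(chromLen))
            pos <- floor(stats::runif(length(todo), 1,
                                      chromLen[ci] - lens[todo]))
            cand <- GRanges(factor(chroms[ci], levels = chroms),
                            IRanges(start = pos, width = lens[todo]))
            hit <- overlapsAny(cand, enhGr, ignore.strand = TRUE)
            ok <- which(!hit)
            chrom[todo[ok]] <- chroms[ci[ok]]
            st[todo[ok]] <- pos[ok]
            todo <- todo[hit]
        }
        if (length(todo) > 0)
            stop("could not place non-overlapping lncRNAs; genome too dense")
    }
    gr <- GRanges(chrom, IRanges(start = st, width = lens))
    GenomeInfoDb::seqlevels(gr) <- seqlevels(layout)
    GenomeInfoDb::seqinfo(gr) <- layout
    mcols(gr)$name <- sprintf("lnc%03d", seq_len(n))
    list(gr = gr,
         truth = data.frame(lncrna_id = mcols(gr)$name,
                            overlaps_enhancer = ovEnh,
                            stringsAsFactors = FALSE))
}

#' Simulate lncRNAs with no enhancer association
#'
#' Places `nLncrnas` loci uniformly at random across the genome,
#' independent of any enhancer, for null calibration of the overlap test.
#'
#' @param config a [simConfig()] list.
#' @param seed RNG seed (defaults to the config seed).
#' @return A GRanges of lncRNA loci.
#' @export
simulateNullOverlap <- function(config = simConfig(), seed = config$seed) {
    stopifnot(inherits(config, "simConfig"))
    withSeed(seed, {
        layout <- genomeLayout(config$chromLengths)
        chroms <- seqlevels(layout)
        chromLen <- as.numeric(seqlengths(layout))
        n <- config$nLncrnas
        lens <- round(stats::runif(n, config$lncrnaLengthRange[1],
                                   config$lncrnaLengthRange[2]))
        ci <- sample.int(length(chroms), n, replace = TRUE,
                         prob = chromLen / sum(chromLen))
        pos <- floor(stats::runif(n, 1, chromLen[ci] - lens))
        gr <- GRanges(chroms[ci], IRanges(start = pos, width = lens))
        GenomeInfoDb::seqlevels(gr) <- chroms
        GenomeInfoDb::seqinfo(gr) <- layout
        mcols(gr)$name <- sprintf("lnc%03d", seq_len(n))
        gr
    })
}
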