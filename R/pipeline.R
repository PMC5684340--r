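#' Default analysis thresholds
#'
#' Every tunable threshold of the pipeline with its default value: minimum
#' per-mark sample support for candidate enhancers (2 of 4), promoter
#' flank (1000 bp), differential log2 fold-change threshold (1, i.e.
#' linear fold 2) at BH q < 0.05, unaffected background band (linear fold
#' <= 1.05), de novo enrichment thresholds (treated > 1.5 with control <
#' 1.1 or vice versa), super-enhancer stitching gap (12.5 kb) and
#' gained/lost fold-change bounds (2 and 0.5) with 0.1 rpm pseudo-signal,
#' gene-assignment windows (250 kb from enhancer edges; 50 kb from region
#' centre), expression floor (100 A.U.), DE rule (coverage >= 10, fold >=
#' 1.5) and permutation count (10000).
#'
#' @return named list of defaults.
#' @export
pipelineDefaults <- function() {
    list(minSupport = 2, promoterFlank = 1000, logfcThreshold = 1,
         qThreshold = 0.05, backgroundBand = 1.05, deNovoHi = 1.5,
         deNovoLo = 1.1, stitchGap = 12500, seGainedFc = 2,
         seLostFc = 0.5, seEpsilon = 0.1, windowEnhancerGene = 250000,
         windowNearestGene = 50000, exprFloor = 100, deMinCoverage = 10,
         deMinFc = 1.5, nSims = 10000)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Orchestrates simulation and every analysis stage, writing plain-text
#' outputs (BED/TSV/JSON) plus a run manifest to `outdir`. Outputs are
#' deterministic given a fixed seed: rerunning with the same seed and
#' configuration reproduces every file byte for byte.
#'
#' @param outdir output directory (created if needed).
#' @param command one of "all", "simulate", "call-enhancers",
#'   "diff-enhancers", "call-ses", "diff-ses", "integrate", "lnc-overlap".
#'   Later stages imply the earlier ones they need; "all" runs everything.
#' @param config thresholds, see [pipelineDefaults()].
#' @param sim simulation configuration, see [simConfig()].
#' @param seed seed applied to the simulation and the permutation test
#'   (overrides `sim$seed`).
#' @param nSims permutation count for the overlap test (defaults to
#'   `config$nSims`; the synthetic genome is small, so a few thousand
#'   suffice).
#' @return Invisibly, a list with the main in-memory results.
#' @export
runPipeline <- function(outdir, command = "all",
                        config = pipelineDefaults(),
                        sim = simConfig(), seed = sim$seed,
                        nSims = config$nSims) {
    commands <- c("all", "simulate", "call-enhancers", "diff-enhancers",
                  "call-ses", "diff-ses", "integrate", "lnc-overlap")
    if (!command %in% commands)
        stop(sprintf("unknown command '%s'", command))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    sim$seed <- seed
    res <- list()

    dat <- simulateExperiment(sim)
    writeChromSizes(dat$layout, file.path(outdir, "chrom_sizes.tsv"))
    writeGeneAnnotation(dat$annotation, file.path(outdir, "genes.tsv"))
    utils::write.table(dat$expression,
                       file.path(outdir, "expression_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeBed(dat$lncrnas, file.path(outdir, "lncrnas.bed"))
    for (nm in names(dat$tracks)) {
        t <- dat$tracks[[nm]]
        if (length(t@peaks) > 0)
            writeBed(t@peaks, file.path(outdir,
                                        sprintf("peaks_%s.bed", nm)))
    }
    utils::write.table(dat$truth$enhancers,
                       file.path(outdir, "truth_enhancers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$data <- dat
    if (command == "simulate") return(.finishRun(res, outdir, sim, config,
                                                 seed))

    marks <- vapply(dat$tracks, function(t) t@mark, character(1))
    acPeaks <- lapply(dat$tracks[marks == "H3K27ac"], function(t) t@peaks)
    me1Peaks <- lapply(dat$tracks[marks == "H3K4me1"], function(t) t@peaks)
    k4me3 <- mergeIntervals(do.call(c, unname(
        lapply(dat$tracks[marks == "H3K4me3"], function(t) t@peaks))))
    cand <- callCandidateEnhancers(acPeaks, me1Peaks,
                                   minSupport = config$minSupport)
    catalog <- filterRegulatory(cand, dat$annotation, k4me3,
                                promoterFlank = config$promoterFlank)
    writeBed(regions(catalog), file.path(outdir, "enhancers.bed"))
    res$catalog <- catalog
    if (command == "call-enhancers") return(.finishRun(res, outdir, sim,
                                                       config, seed))

    enr <- computeEnrichment(catalog, dat$tracks, mark = "H3K27ac")
    diffEnh <- differentialEnhancers(
        enr, logfcThreshold = config$logfcThreshold,
        qThreshold = config$qThreshold,
        backgroundBand = config$backgroundBand,
        deNovoHi = config$deNovoHi, deNovoLo = config$deNovoLo)
    writeDifferentialTable(diffEnh,
                           file.path(outdir, "differential_enhancers.tsv"))
    res$diffEnhancers <- diffEnh
    if (command == "diff-enhancers") return(.finishRun(res, outdir, sim,
                                                       config, seed))

    rankings <- lapply(c(control = "control", treated = "treated"),
                       function(cond)
        callSuperEnhancers(regions(catalog), dat$tracks, cond,
                           gap = config$stitchGap))
    for (cond in names(rankings)) {
        r <- rankings[[cond]]
        writeBed(regions(r),
                 file.path(outdir, sprintf("se_ranking_%s.bed", cond)),
                 extraCols = list(
                     rank = mcols(regions(r))$rank,
                     signal = sprintf("%.4f", mcols(regions(r))$signal),
                     is_SE = as.integer(mcols(regions(r))$isSE)))
    }
    res$rankings <- rankings
    if (command == "call-ses") return(.finishRun(res, outdir, sim, config,
                                                 seed))

    diffSE <- differentialSuperEnhancers(
        rankings$control, rankings$treated, dat$tracks,
        epsilon = config$seEpsilon, gainedFc = config$seGainedFc,
        lostFc = config$seLostFc)
    utils::write.table(
        data.frame(chrom = as.character(seqnames(diffSE)),
                   start = GenomicRanges::start(diffSE) - 1,
                   end = GenomicRanges::end(diffSE),
                   signal_ctrl = mcols(diffSE)$signalCtrl,
                   signal_trt = mcols(diffSE)$signalTrt,
                   fc = mcols(diffSE)$fc, class = mcols(diffSE)$class),
        file.path(outdir, "differential_ses.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
    if (length(diffSE) > 0)
        utils::write.table(seClassSummary(diffSE),
                           file.path(outdir, "se_class_summary.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    res$diffSE <- diffSE
    if (command == "diff-ses") return(.finishRun(res, outdir, sim, config,
                                                 seed))

    au <- normalizedExpression(
        as.matrix(dat$expression[, c("count_ctrl", "count_trt")]))
    rownames(au) <- dat$expression$gene_id
    auC <- stats::setNames(au[, 1], rownames(au))
    auT <- stats::setNames(au[, 2], rownames(au))
    de <- callDeGenes(auC, auT, minCoverage = config$deMinCoverage,
                      minFc = config$deMinFc)
    de$gene_id <- dat$expression$gene_id
    utils::write.table(de[, c("gene_id", "de", "direction", "log2fc")],
                       file.path(outdir, "de_genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    links <- assignEnhancersToGenes(diffEnh, dat$annotation,
                                    window = config$windowEnhancerGene)
    utils::write.table(links, file.path(outdir, "enhancer_gene_links.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    seUniv <- diffSE
    teRegions <- regions(rankings$treated)[!isSE(rankings$treated)]
    roseMap <- mapNearestGenesRose(seUniv, teRegions, dat$annotation,
                                   auC, auT,
                                   window = config$windowNearestGene,
                                   auFloor = config$exprFloor)
    contrib <- NULL
    seGeneRows <- roseMap$regions[roseMap$regions$region_type == "SE", ,
                                  drop = FALSE]
    if (nrow(seGeneRows) > 0) {
        cls <- stats::setNames(
            mcols(seUniv)$class[seGeneRows$region], seGeneRows$gene_id)
        cls <- cls[!duplicated(names(cls))]
        contrib <- contributionSummary(cls, auC, auT)
        utils::write.table(
            data.frame(class = names(contrib$classContribution),
                       contribution_pts = contrib$classContribution,
                       percent_change_total = contrib$percentChange),
            file.path(outdir, "se_expression_contribution.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
    }
    res$au <- au
    res$deGenes <- de
    res$links <- links
    res$roseMap <- roseMap
    res$contribution <- contrib
    if (command == "integrate") return(.finishRun(res, outdir, sim, config,
                                                  seed))

    overlap <- lncrnaOverlapTest(regions(catalog), dat$lncrnas,
                                 dat$layout, nSims = nSims, seed = seed)
    utils::write.table(
        data.frame(k_enhancers = overlap@observedEnhancers,
                   k_lncrnas = overlap@observedLncrnas,
                   null_mean = mean(nullCounts(overlap)),
                   null_sd = stats::sd(nullCounts(overlap)),
                   n_sims = length(nullCounts(overlap)),
                   p_empirical = pValue(overlap)),
        file.path(outdir, "lncrna_overlap.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
    res$overlap <- overlap
    .finishRun(res, outdir, sim, config, seed)
}

.finishRun <- function(res, outdir, sim, config, seed) {
    files <- sort(setdiff(list.files(outdir), "manifest.json"))
    manifest <- list(
        package = "EnhancerScape",
        version = as.character(utils::packageVersion("EnhancerScape")),
        seed = seed,
        config = config,
        simulation = sim[setdiff(names(sim), "chromLengths")],
        chromLengths = as.list(sim$chromLengths),
        outputs = as.list(stats::setNames(
            unname(tools::md5sum(file.path(outdir, files))), files)))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(res)
}
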