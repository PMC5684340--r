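# small, fast configuration for generator-focused checks
smallCfg <- function(seed = 1, ...) {
    args <- list(seed = seed, chromLengths = c(chr1 = 2e7, chr2 = 2e7),
                 nGenes = 160, nEnhancers = 120, nSeClusters = 3,
                 nLncrnas = 30, includeBrd4 = FALSE, nSpuriousPeaks = 20,
                 nDecoys = 12)
    do.call(simConfig, utils::modifyList(args, list(...)))
}

test_that("identical seeds give bit-identical synthetic experiments", {
    d1 <- simulateExperiment(smallCfg(7))
    d2 <- simulateExperiment(smallCfg(7))
    expect_identical(d1$truth, d2$truth)
    expect_identical(d1$expression, d2$expression)
    expect_identical(granges(d1$lncrnas), granges(d2$lncrnas))
    for (nm in names(d1$tracks)) {
        expect_identical(granges(d1$tracks[[nm]]@peaks),
                         granges(d2$tracks[[nm]]@peaks))
        expect_identical(granges(d1$tracks[[nm]]@fragments),
                         granges(d2$tracks[[nm]]@fragments))
    }
    # a different seed changes the data
    d3 <- simulateExperiment(smallCfg(8))
    expect_false(identical(d1$truth$enhancers$start,
                           d3$truth$enhancers$start))
    # the global RNG stream is untouched
    set.seed(123); before <- runif(3)
    set.seed(123); invisible(simulateExperiment(smallCfg(9)))
    expect_identical(runif(3), before)
})

test_that("zero enhancers give empty truth and no planted peaks", {
    d <- simulateExperiment(smallCfg(1, nEnhancers = 0, nSeClusters = 0,
                                     nDecoys = 0, nSpuriousPeaks = 0,
                                     lncrnaOverlapFraction = 0))
    expect_equal(nrow(d$truth$enhancers), 0)
    expect_null(d$truth$clusters)
    expect_equal(length(d$tracks$H3K27ac_control_1@peaks), 0)
    # fragments are pure background; expression table still produced
    expect_equal(nrow(d$expression), 160)
})

test_that("planted class proportions and count models hold", {
    d <- simulateExperiment(smallCfg(2))
    tr <- d$truth$enhancers
    sing <- tr[is.na(tr$cluster_id), ]
    frac <- table(sing$class) / nrow(sing)
    cfg <- smallCfg(2)
    for (k in names(cfg$classFractions))
        expect_lt(abs(frac[[k]] - cfg$classFractions[[k]]), 0.02)
    # counts are non-negative integers
    expect_true(all(d$expression$count_ctrl >= 0))
    expect_true(all(d$expression$count_ctrl == round(d$expression$count_ctrl)))
    expect_true(all(d$expression$count_trt >= 0))
    # negative-binomial option also yields valid integer counts
    dn <- simulateExperiment(smallCfg(2, countNoise = "negative_binomial"))
    expect_true(all(dn$expression$count_trt == round(dn$expression$count_trt)))
    # planted lncRNA overlaps are real overlaps
    ov <- d$truth$lncrnas$overlaps_enhancer
    enhGr <- gr0(tr$chrom, tr$start, tr$end)
    planted <- d$lncrnas[!is.na(ov)]
    expect_true(all(overlapsAny(planted, enhGr)))
    # genome too small to host the request errors out
    expect_error(
        simulateExperiment(simConfig(seed = 1,
                                     chromLengths = c(chr1 = 2e6),
                                     nEnhancers = 200, nSeClusters = 0,
                                     includeBrd4 = FALSE)),
        "genome too small")
})

test_that("cluster constituents stitch and spacing separates singletons", {
    d <- simulateExperiment(smallCfg(3))
    tr <- d$truth$enhancers
    enhGr <- gr0(tr$chrom, tr$start, tr$end)
    st <- stitchEnhancers(enhGr)
    # every planted cluster collapses to one stitched region
    clu <- d$truth$clusters
    for (i in seq_len(nrow(clu))) {
        inSpan <- subsetByOverlaps(st, gr0(clu$chrom[i], clu$span_start[i],
                                           clu$span_end[i]))
        expect_equal(length(inSpan), 1)
        expect_equal(mcols(inSpan)$nConstituents, clu$n_constituents[i])
    }
    # singletons never stitch with anything
    singIdx <- which(is.na(tr$cluster_id))
    hits <- countOverlaps(enhGr[singIdx], st)
    expect_true(all(hits == 1))
    expect_equal(length(st), nrow(clu) + length(singIdx))
})

test_that("recovery sensitivity increases with planted effect size", {
    sens <- vapply(c(0.5, 1.25, 2), function(es) {
        a <- analyzedSim(5, chromLengths = c(chr1 = 2e7, chr2 = 2e7),
                         nGenes = 160, nEnhancers = 120, nSeClusters = 3,
                         nLncrnas = 30, nSpuriousPeaks = 20, nDecoys = 12,
                         effectSize = es)
        recoveryStats(a)$sensitivity
    }, numeric(1))
    expect_true(all(diff(sens) > 0))
    expect_gt(sens[3], 0.9)
})

test_that("null lncRNA placement is uniform and seed-stable", {
    cfg <- smallCfg(4)
    l1 <- simulateNullOverlap(cfg, seed = 11)
    l2 <- simulateNullOverlap(cfg, seed = 11)
    expect_identical(granges(l1), granges(l2))
    expect_equal(length(l1), cfg$nLncrnas)
    expect_true(all(end(l1) <= 2e7))
})
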