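test_that("stitching joins enhancers within the gap", {
    e <- gr0("chr1", c(0, 5000), c(1000, 6000))
    st <- stitchEnhancers(e)
    expect_equal(length(st), 1)
    expect_equal(c(start(st) - 1, end(st)), c(0, 6000))
    expect_equal(mcols(st)$nConstituents, 2L)

    e2 <- c(e, gr0("chr1", 30000, 31000))  # 24 kb away: separate region
    st2 <- stitchEnhancers(e2)
    expect_equal(length(st2), 2)
    # exactly at the gap: end 6000 to start 18500 is 12500 -> stitched
    e3 <- c(e, gr0("chr1", 18500, 19500))
    expect_equal(length(stitchEnhancers(e3)), 1)
    e4 <- c(e, gr0("chr1", 18501, 19501))
    expect_equal(length(stitchEnhancers(e4)), 2)

    expect_equal(length(stitchEnhancers(gr0("chr1", 5, 10))), 1)
    expect_equal(length(stitchEnhancers(GRanges())), 0)

    # order-invariance and base preservation
    set.seed(4)
    s <- sort(sample(1e6, 40))
    g <- gr0("chr1", s, s + 800)
    sh <- g[sample(length(g))]
    expect_equal(granges(stitchEnhancers(g)), granges(stitchEnhancers(sh)))
})

test_that("background-subtracted signal is floored rpm difference", {
    region <- stitchEnhancers(gr0("chr1", 1000, 2000))
    chip <- makeTrack(seq(1100, length.out = 30, by = 10),
                      librarySize = 1e6, id = "c")
    inp <- makeTrack(seq(1100, length.out = 10, by = 10),
                     librarySize = 1e6, id = "i")
    expect_equal(backgroundSubtractedSignal(region, list(chip), list(inp)),
                 20)
    # input exceeding chip floors at zero
    expect_equal(backgroundSubtractedSignal(region, list(inp), list(chip)),
                 0)
    expect_warning(
        s <- backgroundSubtractedSignal(region, list(chip), NULL),
        "no input")
    expect_equal(s, 30)
    # replicates are averaged after scaling
    expect_equal(backgroundSubtractedSignal(region, list(chip, inp),
                                            list(inp)), 10)
})

test_that("rose cutoff finds the slope-one tangency point", {
    rc <- roseCutoff(c(1, 1, 1, 1, 100))
    expect_equal(rc$cutoffSignal, 1)
    expect_equal(sum(rc$isSE), 1)
    expect_true(rc$isSE[5])

    # perfectly linear curve: ties broken to the last index, zero SEs
    rcLin <- roseCutoff(seq(0, 10, length.out = 11))
    expect_equal(sum(rcLin$isSE), 0)

    expect_message(rcFlat <- roseCutoff(rep(3, 6)), "flat")
    expect_equal(sum(rcFlat$isSE), 0)
    expect_error(roseCutoff(5), "at least 2")
    expect_error(roseCutoff(c(-1, 2)), "non-negative")
})

test_that("tangency index matches the slope oracle on convex curves", {
    # for a strictly convex scaled curve, argmax(x - y) is the first index
    # whose forward slope exceeds one
    set.seed(5)
    for (i in 1:100) {
        n <- sample(20:200, 1)
        inc <- sort(rexp(n - 1)) + 1e-9   # increasing increments => convex
        s <- cumsum(c(runif(1), inc))
        rc <- roseCutoff(s)
        xs <- (seq_len(n) - 1) / (n - 1)
        ys <- (s - s[1]) / (s[n] - s[1])
        slope <- diff(ys) / diff(xs)
        oracle <- which(slope > 1)[1]
        expect_equal(rc$cutoffIndex, oracle)
        # geometric check: slope-one line through the tangency point stays
        # at or below the curve
        expect_true(all(ys - (xs - xs[rc$cutoffIndex] + ys[rc$cutoffIndex])
                        >= -1e-9))
    }
})

test_that("differential SE classification uses the fold-change bounds", {
    mkRank <- function(startsKb, signals, se, cond) {
        g <- gr0("chr1", startsKb * 1000, startsKb * 1000 + 2000)
        o <- order(signals)
        g <- g[o]
        mcols(g)$signal <- signals[o]
        mcols(g)$rank <- seq_along(g)
        mcols(g)$isSE <- se[o]
        new("RoseRanking", regions = g, cutoffSignal = min(signals) - 1,
            condition = cond)
    }
    # three SE loci with ctrl/trt signals 10/25 (gained), 10/4 (lost),
    # 10/10 (unchanged); fc uses epsilon 0.1
    starts <- c(100, 300, 500)
    ctrl <- mkRank(starts, c(10, 10, 10.0001), c(TRUE, TRUE, TRUE), "control")
    trt <- mkRank(starts, c(25, 4, 10), c(TRUE, TRUE, TRUE), "treated")
    # counting tracks that realize those rpm signals over 2 kb regions
    frag <- function(n, at) rep(seq(at + 100, by = 1, length.out = n))
    mkT <- function(id, cond, perRegion, mark = "H3K27ac", inputId = NA) {
        makeTrack(unlist(mapply(frag, perRegion, starts * 1000)),
                  librarySize = 1e6, id = id, mark = mark,
                  condition = cond, inputId = inputId)
    }
    tracks <- list(
        mkT("c1", "control", c(15, 15, 15), inputId = "ic"),
        mkT("ic", "control", c(5, 5, 5), mark = "input"),
        mkT("t1", "treated", c(30, 9, 15), inputId = "it"),
        mkT("it", "treated", c(5, 5, 5), mark = "input"))
    dse <- differentialSuperEnhancers(ctrl, trt, tracks)
    expect_equal(mcols(dse)$signalCtrl, c(10, 10, 10))
    expect_equal(mcols(dse)$signalTrt, c(25, 4, 10))
    expect_equal(mcols(dse)$fc, c(25.1 / 10.1, 4.1 / 10.1, 1))
    expect_equal(mcols(dse)$class, c("gained", "lost", "unchanged"))

    # swapping conditions maps gained <-> lost (fc -> 1/fc up to the
    # epsilon asymmetry, well under 1% at these signals)
    fcInv <- (mcols(dse)$signalCtrl + 0.1) / (mcols(dse)$signalTrt + 0.1)
    expect_true(all(abs(fcInv * mcols(dse)$fc - 1) < 0.01))
    expect_equal(fcInv >= 2, mcols(dse)$class == "lost")
    expect_equal(fcInv <= 0.5, mcols(dse)$class == "gained")

    summary <- seClassSummary(dse)
    expect_equal(sort(summary$class), c("gained", "lost", "unchanged"))
    expect_equal(summary$median_length_kb, rep(2, 3), tolerance = 0.01)
})

test_that("planted SE clusters are recovered and classified", {
    a <- analyzedSim(1)
    clu <- a$truth$clusters
    cluGr <- gr0(clu$chrom, clu$span_start, clu$span_end)
    for (cond in c("control", "treated")) {
        r <- a$rankings[[cond]]
        # fewer SEs than typical enhancers on realistic data
        expect_lt(sum(isSE(r)), sum(!isSE(r)))
    }
    # every planted cluster is an SE in the condition where it is active
    seT <- regions(a$rankings$treated)[isSE(a$rankings$treated)]
    expect_true(all(overlapsAny(cluGr[clu$class != "lost"], seT)))
    # differential classes match the planted cluster classes
    h <- findOverlaps(a$diffSE, cluGr)
    called <- mcols(a$diffSE)$class[queryHits(h)]
    expect_equal(called[order(subjectHits(h))], clu$class[sort(subjectHits(h))])
})
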