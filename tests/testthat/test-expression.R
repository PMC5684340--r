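test_that("TMM factors behave on identity, scaling and composition shifts", {
    set.seed(20)
    m <- matrix(rpois(2000, 100), ncol = 2)
    # identical columns -> unit factors
    expect_equal(tmmFactors(cbind(m[, 1], m[, 1])), c(1, 1))
    # pure library-size doubling: M values all zero after scaling
    expect_equal(tmmFactors(cbind(m[, 1], 2 * m[, 1])), c(1, 1))
    expect_error(tmmFactors(cbind(m[, 1], 0 * m[, 1])), "all-zero")
    expect_error(tmmFactors(m[, 1, drop = FALSE]), "at least 2")
    # gene-order invariance
    f <- tmmFactors(m)
    expect_equal(tmmFactors(m[sample(nrow(m)), ]), f)
    # factors multiply to one
    expect_equal(prod(tmmFactors(matrix(rpois(300, 50), ncol = 3))), 1,
                 tolerance = 1e-12)
})

test_that("TMM factors match the edgeR reference on shifted compositions", {
    skip_if_not_installed("edgeR")
    set.seed(21)
    m <- matrix(rnbinom(4000, mu = 100, size = 5), ncol = 4)
    m[1:200, 2] <- m[1:200, 2] * 8
    ref <- edgeR::calcNormFactors(edgeR::DGEList(counts = m))
    expect_equal(tmmFactors(m), ref$samples$norm.factors, tolerance = 1e-4)
})

test_that("TPM is length-normalized and sums to a million", {
    expect_equal(tpm(100, 500)[1, 1], 1e6)
    t2 <- tpm(c(100, 100), c(1000, 2000))
    expect_equal(t2[, 1], c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
    set.seed(22)
    m <- matrix(rpois(300, 40), ncol = 3)
    expect_equal(colSums(tpm(m, runif(100, 200, 5000))),
                 rep(1e6, 3), ignore_attr = TRUE)
    expect_error(tpm(c(1, 2), c(0, 5)), "positive")
})

test_that("DE rule needs coverage 10 in either sample and fold 1.5", {
    # below the coverage floor in both samples: excluded regardless of fc
    d <- callDeGenes(c(2, 20, 100, 0, 30), c(9, 32, 110, 15, 12))
    expect_equal(d$de, c(FALSE, TRUE, FALSE, TRUE, TRUE))
    expect_equal(d$direction, c("none", "up", "none", "up", "down"))
    # coverage exactly 10 and fold exactly 1.5 qualify
    expect_true(callDeGenes(10, 15)$de)
})

test_that("enhancer-gene assignment respects the 250 kb TSS window", {
    ann <- makeGenes(rep("chr1", 3), c(299999, 400000, 101000),
                     ids = c("near", "far", "inside"))
    enh <- gr0("chr1", 100000, 102000)
    links <- assignEnhancersToGenes(enh, ann)
    expect_setequal(links$gene_id, c("near", "inside"))
    expect_equal(links$distance[links$gene_id == "near"], 198000)
    expect_equal(links$distance[links$gene_id == "inside"], 0)
    # a gene can link to several enhancers
    links2 <- assignEnhancersToGenes(c(enh, gr0("chr1", 200000, 201000)),
                                     ann)
    expect_equal(sum(links2$gene_id == "near"), 2)
})

test_that("nearest-gene mapping applies floor, SE priority and ties", {
    ann <- makeGenes(rep("chr1", 4), c(120000, 145000, 310000, 339000),
                     ids = c("low", "ok", "teGene", "shared"))
    au <- c(low = 80, ok = 500, teGene = 300, shared = 300)
    se <- gr0("chr1", 99000, 101000)    # centre 100000
    te <- c(gr0("chr1", 299000, 301000),  # centre 300000 -> teGene
            gr0("chr1", 337000, 339000))  # centre 338000 -> shared
    seBig <- c(se, gr0("chr1", 336000, 338000))  # centre 337000 -> shared
    m <- mapNearestGenesRose(seBig, te, ann, au, au)
    # the 80 A.U. gene at 20 kb is filtered; next gene at 45 kb mapped
    expect_equal(m$regions$gene_id[m$regions$region_type == "SE" &
                                   m$regions$region == 1], "ok")
    expect_lt(abs(m$regions$distance[m$regions$region == 1 &
                                     m$regions$region_type == "SE"] - 45000),
              2)
    # gene near both an SE and a TE is assigned to the SE
    g <- m$genes
    expect_equal(g$link_type[g$gene_id == "shared"], "SE")
    expect_equal(g$link_type[g$gene_id == "teGene"], "TE")
    # expressed gene with no region within 50 kb
    annF <- makeGenes(rep("chr1", 2), c(145000, 700000),
                      ids = c("ok", "lonely"))
    auF <- c(ok = 500, lonely = 500)
    mF <- mapNearestGenesRose(se, GRanges(), annF, auF, auF)
    expect_equal(mF$genes$link_type[mF$genes$gene_id == "lonely"],
                 "no_enhancer")
    # deterministic tie-break: equidistant genes pick the lower gene_id
    annT <- makeGenes(rep("chr1", 2), c(89999, 109999), ids = c("a", "b"))
    auT <- c(a = 500, b = 500)
    mT <- mapNearestGenesRose(se, GRanges(), annT, auT, auT)
    expect_equal(mT$regions$gene_id, "a")
})

test_that("contribution summary conserves the total change", {
    # mirror of the stacked-bar arithmetic: totals 400 -> 500 A.U., gained
    # class contributing +84 of the +100
    au0 <- c(g1 = 100, g2 = 150, g3 = 150)
    au1 <- c(g1 = 184, g2 = 116, g3 = 200)
    cls <- c(g1 = "gained", g2 = "lost", g3 = "unchanged")
    cs <- contributionSummary(cls, au0, au1)
    expect_equal(cs$percentChange, 25)
    expect_equal(unname(cs$classContribution["gained"]), 21)
    expect_equal(sum(cs$classContribution), cs$percentChange)
    # no change
    cs0 <- contributionSummary(cls, au0, au0)
    expect_equal(cs0$percentChange, 0)
    expect_equal(unname(cs0$classContribution), c(0, 0, 0))
    # single class: its contribution is the whole change
    cs1 <- contributionSummary(c(g1 = "gained"), au0, au1)
    expect_equal(unname(cs1$classContribution["gained"]), cs1$percentChange)
    expect_error(contributionSummary(cls, au0 * 0, au1), "zero control")
    # exact conservation on random tables
    set.seed(23)
    for (i in 1:10) {
        n <- 30
        a0 <- setNames(runif(n, 10, 1000), paste0("g", 1:n))
        a1 <- setNames(runif(n, 10, 1000), paste0("g", 1:n))
        k <- setNames(sample(c("gained", "lost", "unchanged"), n, TRUE),
                      names(a0))
        cc <- contributionSummary(k, a0, a1)
        expect_equal(sum(cc$classContribution), cc$percentChange,
                     tolerance = 1e-12)
    }
})

test_that("nearest-rank correlation separates rank-1 from shuffled ranks", {
    set.seed(24)
    n <- 200
    # regions every 100 kb; rank-1 gene at 10 kb, rank-2 gene at 30 kb
    at <- seq(1e5, by = 1e5, length.out = n)
    reg <- gr0("chr1", at, at + 2000)
    lfc <- runif(n, -2, 2)
    mcols(reg)$fc <- 2^lfc
    tss1 <- at + 1000 + 10000
    tss2 <- at + 1000 + 30000
    ann <- makeGenes(rep("chr1", 2 * n), c(tss1, tss2),
                     ids = sprintf("g%04d", seq_len(2 * n)))
    au0 <- setNames(rep(1000, 2 * n), sprintf("g%04d", seq_len(2 * n)))
    # rank-1 genes move exactly with the region; rank-2 genes are permuted
    lfc2 <- sample(lfc)
    au1 <- au0 * 2^c(lfc, lfc2)
    # pseudocount distorts log2 fc slightly; use big AU so it is negligible
    rho <- nearestRankCorrelation(reg, ann, au0, au1, ranks = 1:2)
    expect_gt(rho["rank1"], 0.99)
    expect_lt(abs(rho["rank2"]), 0.2)
    # too few regions for a correlation: missing value
    tiny <- nearestRankCorrelation(reg[1:2], ann, au0, au1, ranks = 1)
    expect_true(is.na(tiny["rank1"]))
    # anti-correlated construction
    au1b <- au0 * 2^c(-lfc, lfc2)
    rhoB <- nearestRankCorrelation(reg, ann, au0, au1b, ranks = 1)
    expect_lt(rhoB["rank1"], -0.99)
})

test_that("genes near planted up enhancers shift expression upward", {
    a <- analyzedSim(1)
    au <- normalizedExpression(
        as.matrix(a$expression[, c("count_ctrl", "count_trt")]))
    rownames(au) <- a$expression$gene_id
    auC <- setNames(au[, 1], rownames(au))
    auT <- setNames(au[, 2], rownames(au))
    links <- assignEnhancersToGenes(a$diffEnh, a$annotation)
    cls <- mcols(a$diffEnh)$class
    lfc <- log2((auT + 1) / (auC + 1))
    # the 250 kb windows tile many enhancers, so group each gene by the
    # class of its closest linked enhancer
    links <- links[order(links$gene_id, links$distance), ]
    closest <- links[!duplicated(links$gene_id), ]
    grp <- cls[closest$enhancer]
    upGenes <- closest$gene_id[grp %in% c("up", "de_novo_gained")]
    flatGenes <- closest$gene_id[grp %in% c("unaffected_background",
                                            "other")]
    expect_gt(length(upGenes), 20)
    expect_gt(length(flatGenes), 20)
    w <- wilcox.test(lfc[upGenes], lfc[flatGenes], alternative = "greater")
    expect_lt(w$p.value, 0.01)
    expect_gt(mean(lfc[upGenes]) - mean(lfc[flatGenes]), 0.5)
})
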