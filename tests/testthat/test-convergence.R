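test_that("relative tip rates remove gene-wide scale and flag lineage shifts", {
    st <- makeSpeciesTree(12, c(2, 1), seed = 3)
    # gene tree = species tree x 2: all centered rates are zero
    g2 <- asPhylo(st); g2$edge.length <- g2$edge.length * 2
    r <- relativeTipRates(taggedTree(g2), st)
    expect_lt(max(abs(r)), 1e-10)

    # halving one terminal branch drives that tip's rate negative
    gh <- asPhylo(st)
    term <- which(gh$edge[, 2] == 1L)
    gh$edge.length[term] <- gh$edge.length[term] * 0.5
    rh <- relativeTipRates(taggedTree(gh), st)
    tip1 <- gh$tip.label[1]
    expect_lt(rh[tip1], 0)
    expect_lt(max(abs(rh[setdiff(names(rh), tip1)])), 0.05)
})

test_that("constrained genes slow the foreground relative to the background", {
    st <- makeSpeciesTree(20, c(2, 2, 1), seed = 5)
    g <- simulateGeneTrees(st, 200, 1, rateMultiplier = 0.3,
                           lognormalNoiseSd = 0.2, missingFrac = 0,
                           seed = 6)
    fg <- foregroundTips(st)
    ratio <- vapply(g$trees, function(gt) {
        d <- rootToTip(gt)
        mean(d[fg]) / mean(d[setdiff(names(d), fg)])
    }, numeric(1))
    expect_lt(mean(ratio), 1)
    rbar <- rowMeans(vapply(g$trees, function(gt) {
        r <- relativeTipRates(gt, st)
        c(mean(r[intersect(fg, names(r))]),
          mean(r[setdiff(names(r), fg)]))
    }, numeric(2)))
    expect_lt(rbar[1], rbar[2])
})

test_that("the permutation test is degenerate-null exact and scale invariant", {
    st <- makeSpeciesTree(16, c(2, 2), seed = 2)
    res <- convergenceTest(st, st, nPerm = 99, seed = 1)
    expect_equal(res$statistic, 0, tolerance = 1e-10)
    expect_equal(res$p, 1)

    g <- simulateGeneTrees(st, 1, 1, rateMultiplier = 0.3, seed = 3,
                           missingFrac = 0)$trees[[1]]
    t1 <- convergenceTest(g, st, nPerm = 99, seed = 4)
    gs <- asPhylo(g); gs$edge.length <- gs$edge.length * 7.3
    t2 <- convergenceTest(taggedTree(gs, foreground = foregroundTips(g)),
                          st, nPerm = 99, seed = 4)
    expect_equal(t1$statistic, t2$statistic, tolerance = 1e-10)
    expect_equal(t1$p, t2$p)

    # formula floor: all permuted |T| below |T| gives (1)/(nPerm+1)
    expect_gte(t1$p, 1 / 100)

    skip <- convergenceTest(pruneTo(g, head(tipLabels(g), 3)), st,
                            nPerm = 9, seed = 1)
    expect_null(skip)
})

test_that("planted constrained genes are recalled with the right sign", {
    st <- makeSpeciesTree(30, c(2, 2, 2, 2, 1, 1), seed = 1)
    g <- simulateGeneTrees(st, 40, 0.5, rateMultiplier = 0.3,
                           lognormalNoiseSd = 0.2, seed = 3)
    res <- convergenceScan(g$trees, st, nPerm = 199, seed = 1)
    m <- merge(res, g$truth, by = "gene_id")
    con <- m$convergence_class == "constrained"
    expect_gte(mean(m$p[con] < 0.05 & m$direction[con] == "constrained"),
               0.5)
    expect_lte(mean(m$direction[con] == "accelerated"), 0.05)
})

test_that("random clade taggings honor the size profile", {
    st <- makeSpeciesTree(30, c(2, 2, 2, 2, 1, 1), seed = 1)
    for (s in 1:5) {
        fg <- randomCladeTagging(st, c(2, 2, 2, 2, 1, 1), seed = s)
        expect_length(fg, 10)
        prof <- duiconverge:::.maximalCladeSizes(
            asPhylo(st), match(fg, tipLabels(st)))
        # placements can merge adjacent groups, never split below profile
        expect_equal(sum(prof), 10L)
        expect_gte(sum(prof >= 2), 4)
    }
})

test_that("the control harness ranks planted signal first", {
    st <- makeSpeciesTree(26, c(2, 2, 2, 1), seed = 8)
    g <- simulateGeneTrees(st, 30, 0.4, rateMultiplier = 0.3, seed = 9)
    ctrl <- controlScan(g$trees, st, nRandom = 8, randomTagSize = 7,
                        nPerm = 99, seed = 10)
    expect_equal(ncol(ctrl$pValues), 10)   # true + 8 random + phylo
    expect_equal(ctrl$trueRank, 1)
    expect_equal(ctrl$summary$run[1], "true")

    ctrl0 <- controlScan(g$trees[1:4], st, nRandom = 0, nPerm = 49,
                         seed = 1)
    expect_setequal(ctrl0$summary$run, c("true", "phylo"))
    expect_true(is.na(ctrl0$trueRank))
})
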