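test_that("sex-bias labels follow the median-of-operators 70% rule", {
    expect_equal(classifySexBias(c(0.75, 0.72, 0.71)), "male_biased")
    expect_equal(classifySexBias(c(0.20, 0.25, 0.28)), "female_biased")
    expect_equal(classifySexBias(c(0.5, 0.6, 0.4)), "unassigned")
    expect_equal(classifySexBias(0.70), "male_biased")     # inclusive >=
    expect_equal(classifySexBias(0.30), "female_biased")
    expect_error(classifySexBias(numeric(0)), "no operator")
    expect_error(classifySexBias(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("CPM filtering keeps a feature iff any sample reaches 2 cpm", {
    L <- rep(1e6, 8)
    cnt <- rbind(allLow = rep(1.9, 8),       # 1.9 cpm everywhere
                 oneAt2 = c(2, rep(0, 7)),   # exactly 2 cpm once
                 zero = rep(0, 8),
                 high = rep(50, 8))
    # pad library sizes to 1e6 with a filler feature
    filler <- 1e6 - colSums(cnt)
    mat <- rbind(cnt, filler = filler)
    colnames(mat) <- sprintf("s%d", 1:8)
    keep <- cpmFilter(mat)
    expect_true("oneAt2" %in% keep)
    expect_true("high" %in% keep)
    expect_false("allLow" %in% keep)
    expect_false("zero" %in% keep)
})

test_that("TMM factors match the straight-line oracle", {
    set.seed(21)
    cnt <- matrix(rnbinom(3000 * 6, mu = rep(rlnorm(3000, 4, 1), 6),
                          size = 5), 3000, 6)
    cnt[, 3] <- cnt[, 3] * 3    # library scale distortion
    dimnames(cnt) <- list(sprintf("f%04d", 1:3000), sprintf("s%d", 1:6))
    tmm <- tmmFactors(cnt)
    expect_equal(unname(tmm$factors), naiveTmmFactors(cnt),
                 tolerance = 1e-6)
    # identical samples: all factors 1
    same <- matrix(rep(c(10, 40, 200, 7), 5), ncol = 5,
                   dimnames = list(letters[1:4], sprintf("s%d", 1:5)))
    expect_equal(unname(tmmFactors(same)$factors), rep(1, 5))
    # permuting samples permutes factors
    perm <- c(4, 1, 6, 3, 2, 5)
    tmm2 <- tmmFactors(cnt[, perm])
    expect_equal(unname(tmm2$factors), unname(tmm$factors[perm]),
                 tolerance = 1e-10)
})

test_that("the empirical-null deposition test calls planted features only", {
    sim <- simulateCounts(nFeatures = 3000, deFrac = 0.05, lfcMean = 3,
                          dispersion = 0.1, seed = 13)
    ex <- expressionStage(sim$counts, nNull = 4e4, seed = 14)
    res <- ex$results
    truthDe <- sim$truth$feature_id[sim$truth$is_de]
    recall <- mean(intersect(truthDe, res$feature_id) %in%
                   res$feature_id[res$called])
    expect_gte(recall, 0.8)
    expect_lte(mean(res$called[!res$feature_id %in% truthDe]), 0.05)

    # a feature identical across samples is never called
    flat <- res[res$feature_id == res$feature_id[1], ]
    norm <- ex$norm
    norm[1, ] <- 100
    res2 <- deTest(norm[1:200, ], biasLabel(sim$counts), nNull = 5e3,
                   seed = 1)
    expect_equal(res2$M[1], 0)
    expect_equal(res2$D[1], 0)
    expect_false(res2$called[1])

    expect_error(deTest(norm[1:50, ], biasLabel(sim$counts), nNull = 10,
                        q = 0.95), "cannot resolve")
})

test_that("deposition calls are invariant to global library rescaling", {
    sim <- simulateCounts(nFeatures = 1500, deFrac = 0.04, lfcMean = 3,
                          seed = 3)
    cnt <- counts(sim$counts)
    ex1 <- expressionStage(sim$counts, nNull = 2e4, seed = 5)
    scaled <- eggCounts(round(cnt * 3), sexRatio(sim$counts),
                        biasLabel(sim$counts))
    ex2 <- expressionStage(scaled, nNull = 2e4, seed = 5)
    shared <- intersect(ex1$results$feature_id, ex2$results$feature_id)
    a <- ex1$results[match(shared, ex1$results$feature_id), ]
    b <- ex2$results[match(shared, ex2$results$feature_id), ]
    expect_gte(mean(a$called == b$called), 0.99)
})

test_that("Spearman correlation uses the exact small-sample distribution", {
    expect_equal(sexratioCorrelation(1:8, 1:8)$rho, 1)
    expect_equal(sexratioCorrelation(1:8, 8:1)$rho, -1)
    # exact two-sided p for a perfect ranking equals 2 / 8!
    expect_equal(sexratioCorrelation(1:8, 1:8)$p, 2 / factorial(8),
                 tolerance = 1e-12)
    # general case: exhaustive enumeration over 6! permutations
    x <- c(3, 1, 4, 1.5, 5, 9)
    y <- c(2.7, 1.8, 2.8, 1.2, 8.2, 8.9)
    got <- sexratioCorrelation(x, y)
    P <- allPerms(6)
    rx <- rank(x)
    rhoAll <- apply(P, 1, function(pm) cor(rx, rank(y)[pm]))
    rhoObs <- cor(rx, rank(y))
    pOracle <- 2 * min(mean(rhoAll >= rhoObs - 1e-12),
                       mean(rhoAll <= rhoObs + 1e-12))
    expect_equal(got$p, min(pOracle, 1), tolerance = 1e-9)
    expect_warning(flat <- sexratioCorrelation(rep(2, 8), 1:8),
                   "constant")
    expect_true(is.na(flat$rho))
})

test_that("called-and-correlated features are a subset of called features", {
    sim <- simulateCounts(nFeatures = 1200, deFrac = 0.05, lfcMean = 3,
                          seed = 8)
    ex <- expressionStage(sim$counts, nNull = 2e4, seed = 9)
    res <- ex$results
    both <- res$called & !is.na(res$p_rho) & res$p_rho < 0.05
    expect_true(all(which(both) %in% which(res$called)))
    expect_lte(sum(both), sum(res$called))
})
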