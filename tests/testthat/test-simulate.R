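test_that("species trees carry the requested foreground clades and subclasses", {
    st <- makeSpeciesTree(36, c(2, 2, 2, 2, 1, 1), seed = 1)
    expect_equal(ape::Ntip(asPhylo(st)), 36)
    fg <- foregroundTips(st)
    expect_length(fg, 10)
    prof <- duiconverge:::.maximalCladeSizes(asPhylo(st),
                                             match(fg, tipLabels(st)))
    expect_equal(sort(prof), sort(c(2, 2, 2, 2, 1, 1)))
    expect_equal(sort(unique(unname(subclassLabels(st)))),
                 c("A", "B", "C"))
    # each subclass is monophyletic by construction
    expect_equal(checkSubclassMonophyly(st)$status, "pass")

    tiny <- makeSpeciesTree(7, c(1), seed = 7)
    expect_length(foregroundTips(tiny), 1)

    expect_error(makeSpeciesTree(5, c(2, 2), seed = 1),
                 "impossible clade placement")

    # determinism: same seed gives byte-identical Newick
    expect_identical(writeNewick(makeSpeciesTree(36, c(2, 2, 1), seed = 9)),
                     writeNewick(makeSpeciesTree(36, c(2, 2, 1), seed = 9)))
})

test_that("gene-tree simulation respects class fractions and degenerate limits", {
    st <- makeSpeciesTree(20, c(2, 1), seed = 2)
    g <- simulateGeneTrees(st, 100, 0.2, rateMultiplier = 0.3,
                           lognormalNoiseSd = 0.2, missingFrac = 0.1,
                           seed = 3)
    expect_equal(sum(g$truth$convergence_class == "constrained"), 20)
    expect_equal(length(g$trees), 100)
    expect_setequal(g$truth$gene_id, names(g$trees))

    # no noise, multiplier 1, no missing: every gene tree is the species
    # tree up to a global scalar
    g0 <- simulateGeneTrees(st, 5, 0, rateMultiplier = 1,
                            lognormalNoiseSd = 0, missingFrac = 0,
                            seed = 4)
    for (gt in g0$trees) {
        ratio <- rootToTip(gt) / rootToTip(st)[tipLabels(gt)]
        expect_lt(diff(range(ratio)), 1e-10)
    }
    expect_error(simulateGeneTrees(st, 5, 0.2, rateMultiplier = 0,
                                   seed = 1), "rateMultiplier")
})

test_that("codon simulation honors the zero-branch limit and determinism", {
    star <- taggedTree(ape::read.tree(text = "(A:0,B:0,C:0);"))
    aln <- simulateCodonAlignment(star, 50, omegaBg = 0.5, seed = 6)
    m <- alignmentMatrix(aln)
    expect_equal(m["A", ], m["B", ])
    expect_equal(m["A", ], m["C", ])

    st <- makeSpeciesTree(8, c(2), seed = 3)
    a1 <- simulateCodonAlignment(st, 30, omegaBg = 0.4, seed = 11)
    a2 <- simulateCodonAlignment(st, 30, omegaBg = 0.4, seed = 11)
    expect_identical(alignmentMatrix(a1), alignmentMatrix(a2))
    noBl <- asPhylo(st); noBl$edge.length <- NULL
    expect_error(simulateCodonAlignment(taggedTree(noBl), 10, 0.5),
                 "branch lengths")
})

test_that("count simulation plants the sex-ratio-linked fold change", {
    sim <- simulateCounts(nFeatures = 4000, nSamples = 8, deFrac = 0.125,
                          lfcMean = 2, dispersion = 0.1, seed = 11)
    cnt <- counts(sim$counts)
    expect_equal(dim(cnt), c(4000L, 8L))
    expect_equal(sum(sim$truth$is_de), 500)
    grp <- biasLabel(sim$counts)
    sr <- sexRatio(sim$counts)
    dx <- abs(mean(sr[grp == grp[1]]) - mean(sr[grp != grp[1]]))
    cpm <- t(t(cnt) / colSums(cnt)) * 1e6
    de <- sim$truth$is_de
    ratio <- log2((rowMeans(cpm[de, grp == grp[1]]) + 0.5) /
                  (rowMeans(cpm[de, grp != grp[1]]) + 0.5))
    # planted |group log2 ratio| concentrates near lfc x mean-ratio gap
    expect_lt(abs(median(abs(ratio)) - 2 * dx), 0.5)

    # null construction: no feature tracks the sex ratio beyond chance
    sim0 <- simulateCounts(nFeatures = 1000, deFrac = 0, seed = 12)
    cpm0 <- t(t(counts(sim0$counts)) / colSums(counts(sim0$counts))) * 1e6
    ps <- apply(cpm0[1:500, ], 1, function(v)
        suppressWarnings(cor.test(v, sexRatio(sim0$counts),
                                  method = "spearman")$p.value))
    expect_lt(mean(ps < 0.05), 0.1)
    expect_error(simulateCounts(100, dispersion = 0), "dispersion")
})

test_that("interactome simulation wires the planted module deterministically", {
    A <- sprintf("n%03d", 1:5); B <- sprintf("n%03d", 6:10)
    sim <- simulateInteractome(40, 0.02, A, B, plantedEdgeProb = 1,
                               seed = 7)
    el <- igraph::as_edgelist(asIgraph(sim$graph))
    cross <- sum((el[, 1] %in% A & el[, 2] %in% B) |
                 (el[, 1] %in% B & el[, 2] %in% A))
    expect_gte(cross, 25)
    expect_true(all(igraph::E(asIgraph(sim$graph))$score >= 0.4))

    sim2 <- simulateInteractome(40, 0.02, A, B, plantedEdgeProb = 1,
                                seed = 7)
    expect_identical(igraph::as_edgelist(asIgraph(sim2$graph)), el)
    expect_error(simulateInteractome(40, -0.1, A, B, 0.5, seed = 1),
                 "\\[0, 1\\]")
    expect_error(simulateInteractome(40, 0.5, A, B, 0.2, seed = 1),
                 ">= backgroundEdgeProb")
})

test_that("hit tables pass the filters as configured and respect bias = 1", {
    gi <- simulateGeneIntervals(100, focalGenes = 10, seed = 1)
    sim <- simulateHitTable(gi, 5, 30, focalGeneBias = 1, seed = 2,
                            passFraction = 1)
    expect_equal(nrow(sim$hits), 150)
    kept <- filterHits(sim$hits)
    expect_gte(nrow(kept) / nrow(sim$hits), 0.9)  # only width-capped fail

    # unbiased placement: focal hit share within a binomial interval of
    # the focal length share
    wFocal <- sum(gi$end[gi$focal] - gi$start[gi$focal]) /
        sum(gi$end - gi$start)
    share <- mean(sim$truth$host_focal)
    ci <- qbinom(c(0.005, 0.995), nrow(sim$hits), wFocal) / nrow(sim$hits)
    expect_gte(share, ci[1]); expect_lte(share, ci[2])

    expect_error(simulateHitTable(gi[0, ], 5, 10, 1, 1), "empty")
    expect_error(simulateHitTable(gi, 5, 10, focalGeneBias = 0.5, 1),
                 ">= 1")
})
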