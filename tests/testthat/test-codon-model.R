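test_that("GY94 generator has the required structure", {
    u <- rep(1 / 61, 61)
    Q <- gy94RateMatrix(kappa = 2, omega = 0.5, freqs = u,
                        normalize = FALSE)
    expect_lt(max(abs(rowSums(Q))), 1e-12)

    # omega = 0 removes every nonsynonymous rate
    tabs <- oracleCodonTables()
    Q0 <- gy94RateMatrix(2, 0, u, normalize = FALSE)
    ns <- outer(tabs$aa, tabs$aa, "!=")
    expect_true(all(Q0[ns] == 0))

    # kappa = 1, omega = 1, uniform frequencies: symmetric generator
    Q1 <- gy94RateMatrix(1, 1, u, normalize = FALSE)
    expect_lt(max(abs(Q1 - t(Q1))), 1e-14)

    # matches the independently built generator for random parameters
    set.seed(2)
    for (i in 1:3) {
        k <- runif(1, 0.5, 5); w <- runif(1, 0.05, 2)
        f <- rgamma(61, 1); f <- f / sum(f)
        expect_equal(unname(gy94RateMatrix(k, w, f, normalize = FALSE)),
                     oracleQ(k, w, f, tabs), tolerance = 1e-12)
    }
})

test_that("codon log-likelihood matches exhaustive state enumeration", {
    u <- rep(1 / 61, 61)
    tabs <- oracleCodonTables()
    nwk <- "((A:0.2,B:0.35):0.15,C:0.4);"
    set.seed(9)
    for (rep in 1:3) {
        idx <- matrix(sample.int(61, 6, replace = TRUE), 3, 2,
                      dimnames = list(c("A", "B", "C"), NULL))
        aln <- new("CodonAlignment", codons = idx)
        # one-ratio model
        tt <- parseNewick(nwk)
        ll <- codonLoglik(aln, tt, kappa = 2, omegaBg = 0.5, freqs = u)
        llB <- bruteLoglik3(idx, 0.2, 0.35, 0.15, 0.4, 2, 0.5, u)
        expect_equal(ll, llB, tolerance = 1e-8)
        # two-ratio model, foreground = terminal branch of A
        ttf <- parseNewick(nwk, foreground = "A")
        ll2 <- codonLoglik(aln, ttf, kappa = 2, omegaBg = 0.5,
                           omegaFg = 0.1, freqs = u)
        llB2 <- bruteLoglik3(idx, 0.2, 0.35, 0.15, 0.4, 2, 0.5, u,
                             omegaA = 0.1)
        expect_equal(ll2, llB2, tolerance = 1e-8)
    }
})

test_that("likelihood respects site independence and pattern compression", {
    u <- rep(1 / 61, 61)
    tt <- parseNewick("((A:0.2,B:0.3):0.1,C:0.25);")
    idx <- matrix(c(5L, 9L, 13L), 3, 1,
                  dimnames = list(c("A", "B", "C"), NULL))
    one <- codonLoglik(new("CodonAlignment", codons = idx), tt,
                       kappa = 2, omegaBg = 0.4, freqs = u)
    two <- codonLoglik(new("CodonAlignment",
                           codons = cbind(idx, idx)), tt,
                       kappa = 2, omegaBg = 0.4, freqs = u)
    expect_equal(two, 2 * one, tolerance = 1e-10)

    # column permutation leaves the likelihood unchanged
    aln <- simulateCodonAlignment(parseNewick("((A:0.2,B:0.3):0.1,C:0.25);"),
                                  40, omegaBg = 0.5, seed = 3)
    perm <- new("CodonAlignment",
                codons = alignmentMatrix(aln)[, sample(40)])
    expect_equal(codonLoglik(aln, tt, 2, 0.5, freqs = u),
                 codonLoglik(perm, tt, 2, 0.5, freqs = u),
                 tolerance = 1e-9)
})

test_that("alignment construction rejects in-frame stops and frame errors", {
    expect_error(codonAlignment(c(A = "ATGTAAGGG")), "stop codon")
    expect_error(codonAlignment(c(A = "ATGC")), "divisible by 3")
    aln <- codonAlignment(c(A = "ATG---GGG", B = "ATGAAAGGG"))
    expect_equal(unname(alignmentMatrix(aln)["A", 2]), 0L)  # gap = missing
    # FASTA round trip preserves the codon index matrix
    tmp <- tempfile(fileext = ".fa")
    writeCodonFasta(aln, tmp)
    expect_identical(alignmentMatrix(readCodonFasta(tmp)),
                     alignmentMatrix(aln))
    unlink(tmp)
})

test_that("the branch-model LRT collapses cleanly and recovers the sign", {
    tt <- parseNewick("((A:0.2,B:0.3):0.1,(C:0.2,D:0.15):0.2);")
    aln <- simulateCodonAlignment(tt, 60, omegaBg = 0.4, seed = 2)
    fit0 <- branchModelLrt(aln, tt, seed = 1)   # no foreground branches
    expect_equal(fit0$lambda, 0)
    expect_equal(fit0$deltaOmega, 0)
    expect_equal(fit0$p, 1)

    st <- makeSpeciesTree(10, c(2, 1), seed = 2)
    aln1 <- simulateCodonAlignment(st, 300, omegaBg = 0.5, omegaFg = 0.1,
                                   kappa = 2, seed = 11)
    fit <- branchModelLrt(aln1, st, seed = 3)
    expect_true(fit$converged)
    expect_gte(fit$lnL1, fit$lnL0 - 1e-6)
    expect_lt(fit$deltaOmega, 0)
    # parameter recovery within 25% relative error at this design size
    expect_lt(abs(fit$omegaBg - 0.5) / 0.5, 0.25)
})
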