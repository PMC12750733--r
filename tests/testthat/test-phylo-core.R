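test_that("Newick parsing validates input and round-trips losslessly", {
    tt <- parseNewick("((A:1,B:1):1,C:2);")
    expect_s4_class(tt, "TaggedTree")
    expect_setequal(tipLabels(tt), c("A", "B", "C"))
    d <- rootToTip(tt)
    expect_equal(unname(d["A"]), 2)

    expect_error(parseNewick("((A:1,A:1):1,C:2);"), "duplicate tip label")
    expect_error(parseNewick("((A:1,B:1:1,C:2);"), "unbalanced")

    for (s in 1:3) {
        tr <- randomTree(12, s)
        nwk <- writeNewick(taggedTree(tr))
        back <- parseNewick(nwk)
        expect_equal(sort(tipLabels(back)), sort(tr$tip.label))
        d1 <- rootToTip(taggedTree(tr))
        d2 <- rootToTip(back)
        expect_equal(d2[names(d1)], d1, tolerance = 1e-9)
        expect_identical(writeNewick(back), nwk)  # idempotent
    }
})

test_that("root-to-tip distances equal brute-force path walks", {
    tt <- parseNewick("((A:1,B:1):1,C:2);")
    expect_equal(rootToTip(tt), c(A = 2, B = 2, C = 2))

    z <- ape::read.tree(text = "((A:0,B:0):0,C:0);")
    expect_equal(unname(rootToTip(taggedTree(z))), c(0, 0, 0))

    tr <- randomTree(50, 7)
    d <- rootToTip(taggedTree(tr))
    # oracle: explicit parent-pointer walk per tip
    for (i in seq_len(ape::Ntip(tr))) {
        dd <- 0; node <- i
        repeat {
            row <- which(tr$edge[, 2] == node)
            if (!length(row)) break
            dd <- dd + tr$edge.length[row]
            node <- tr$edge[row, 1]
        }
        expect_equal(unname(d[tr$tip.label[i]]), dd, tolerance = 1e-12)
    }
    expect_error(rootToTip(taggedTree(ape::unroot(randomTree(6, 1)))),
                 "rooted")
})

test_that("contrasts have the closed form on a cherry and vanish on constants", {
    tt <- parseNewick("(A:1,B:1);")
    u <- picContrasts(tt, c(A = 1, B = 3))
    expect_equal(unname(u), (1 - 3) / sqrt(2), tolerance = 1e-12)

    tr <- taggedTree(randomTree(15, 3))
    x <- setNames(rep(2.5, 15), tipLabels(tr))
    expect_true(all(abs(picContrasts(tr, x)) < 1e-12))

    # linearity in the tip values
    y1 <- setNames(rnorm(15), tipLabels(tr))
    y2 <- setNames(rnorm(15), tipLabels(tr))
    expect_equal(picContrasts(tr, y1 + 2 * y2),
                 picContrasts(tr, y1) + 2 * picContrasts(tr, y2),
                 tolerance = 1e-10)
})

test_that("contrasts whiten the phylogenetic covariance (GLS oracle)", {
    for (s in 1:5) {
        tr <- randomTree(20, 100 + s)
        tt <- taggedTree(tr)
        U <- picLinearMap(tt, tr$tip.label)
        C <- ape::vcv(tr)[tr$tip.label, tr$tip.label]
        W <- U %*% C %*% t(U)
        expect_lt(max(abs(W - diag(nrow(W)))), 1e-8)
    }
})

test_that("contrasts of Brownian tip values are standard normal", {
    tr <- randomTree(15, 9)
    tt <- taggedTree(tr)
    set.seed(10)
    u <- unlist(lapply(1:100, function(i)
        picContrasts(tt, ape::rTraitCont(tr, sigma = 1))))
    ks <- suppressWarnings(ks.test(u, "pnorm"))
    expect_gt(ks$p.value, 0.01)
})

test_that("tip values round-trip through the 2-column TSV interface", {
    v <- setNames(c(0.12, 3.4, 2.25), c("spA", "spB", "spC"))
    tmp <- tempfile(fileext = ".tsv")
    writeTipValues(v, tmp)
    expect_equal(readTipValues(tmp), v)
    unlink(tmp)
})

test_that("tips without values are pruned before contrasts", {
    tr <- taggedTree(randomTree(10, 5))
    x <- setNames(rnorm(6), tipLabels(tr)[1:6])
    u <- picContrasts(tr, x)
    expect_length(u, 5)
    expect_true(all(is.finite(u)))
    expect_error(picContrasts(tr, setNames(1:3, c("zz1", "zz2", "zz3"))),
                 "not among")
})

test_that("foreground branch classes cover exactly the all-foreground subtrees", {
    tt <- parseNewick("(((A:1,B:1):1,C:1):1,(D:1,E:1):1);",
                      foreground = c("A", "B"))
    tr <- asPhylo(tt)
    fe <- foregroundEdges(tt)
    # terminal branches of A and B plus their stem
    tipIdx <- match(c("A", "B"), tr$tip.label)
    childIsFgTip <- tr$edge[fe, 2] %in% tipIdx
    expect_equal(sum(childIsFgTip), 2)
    expect_length(fe, 3)
    feNoStem <- foregroundEdges(tt, stem = "exclude")
    expect_length(feNoStem, 2)
    expect_length(foregroundEdges(taggedTree(tr)), 0)
})

test_that("pruning keeps tags and subclass labels consistent", {
    tt <- parseNewick("((A:1,B:1):1,(C:1,D:1):1);",
                      foreground = c("A", "C"),
                      subclass = c(A = "x", B = "x", C = "y", D = "y"))
    pt <- pruneTo(tt, c("A", "B", "C"))
    expect_setequal(tipLabels(pt), c("A", "B", "C"))
    expect_setequal(foregroundTips(pt), c("A", "C"))
    expect_equal(unname(subclassLabels(pt)[c("A", "C")]), c("x", "y"))
    expect_error(pruneTo(tt, "A"), "fewer than 2")
})
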