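test_that("column and sequence trimming follow the 50%/80% rules", {
    og <- orthoGroup("og1", c(s1 = "AC-D", s2 = "A--D", s3 = "A--D",
                              s4 = "ACMD"))
    tr <- trimAlignment(og)
    # column 3 is gap in 3/4 > 0.5 -> dropped; column 2 gap in 2/4 stays
    expect_equal(tr$removedColumns, 3L)
    expect_equal(ncol(alignmentMatrix(tr$og)), 3L)
    expect_false(tr$empty)

    # sequence with > 80% gaps after column trim is dropped
    seqs <- c(s1 = paste(rep("A", 100), collapse = ""),
              s2 = paste(rep("A", 100), collapse = ""),
              s3 = paste(c(rep("-", 85), rep("A", 15)), collapse = ""))
    tr2 <- trimAlignment(orthoGroup("og2", seqs))
    expect_equal(tr2$removedSequences, "s3")
    expect_equal(nrow(alignmentMatrix(tr2$og)), 2L)

    # gap-free alignment is untouched, and trimming is idempotent
    og3 <- orthoGroup("og3", c(a = "MKV", b = "MRV", c = "MKV"))
    tr3 <- trimAlignment(og3)
    expect_identical(alignmentMatrix(tr3$og), alignmentMatrix(og3))
    tr3b <- trimAlignment(tr3$og)
    expect_identical(alignmentMatrix(tr3b$og), alignmentMatrix(tr3$og))

    # absent species count as missing when a universe size is supplied
    og4 <- orthoGroup("og4", c(a = "MK", b = "MK"))
    tr4 <- trimAlignment(og4, nSpeciesTotal = 5)
    expect_true(tr4$empty)   # 3 absent of 5 > 50% in every column
})

test_that("subclass monophyly is validated with small-set rescue", {
    sub <- c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B",
             c1 = "C", c2 = "C")
    good <- parseNewick(
        "(((a1:1,a2:1):1,a3:1):1,((b1:1,b2:1):1,(c1:1,c2:1):1):1);",
        subclass = sub)
    expect_equal(checkSubclassMonophyly(good)$status, "pass")

    # one B tip nested inside the A clade
    bad <- parseNewick(
        "(((a1:1,b1:1):1,(a2:1,a3:1):1):1,(b2:1,(c1:1,c2:1):1):1);",
        subclass = sub)
    chk <- checkSubclassMonophyly(bad)
    expect_equal(chk$status, "fail")
    expect_true(length(chk$offending) >= 1 && length(chk$offending) <= 2)
    rescued <- pruneTo(bad, setdiff(tipLabels(bad), chk$offending))
    expect_equal(checkSubclassMonophyly(rescued)$status, "pass")

    # deeply interleaved subclasses admit no 1-2-tip fix: brute force over
    # all small subsets must agree with the empty offending set
    tangled <- parseNewick(
        paste0("(((a1:1,b1:1):1,(a2:1,b2:1):1):1,",
               "((a3:1,c1:1):1,(b3:1,c2:1):1):1);"),
        subclass = c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B",
                     b3 = "B", c1 = "C", c2 = "C"))
    chk2 <- checkSubclassMonophyly(tangled)
    expect_equal(chk2$status, "fail")
    expect_length(chk2$offending, 0)

    twoSub <- parseNewick("((a1:1,a2:1):1,(b1:1,b2:1):1);",
                          subclass = c(a1 = "A", a2 = "A",
                                       b1 = "B", b2 = "B"))
    expect_warning(chkV <- checkSubclassMonophyly(twoSub), "vacuous")
    expect_equal(chkV$status, "pass")
})

test_that("orthogroup retention applies the 15-species/4-DUI boundaries", {
    tab <- data.frame(og_id = c("x", "y", "z"),
                      n_species = c(15, 14, 20),
                      n_foreground = c(4, 6, 3))
    out <- filterOrthogroups(tab)
    expect_equal(out$retained, c(TRUE, FALSE, FALSE))
    # idempotent and order-stable
    again <- filterOrthogroups(out[out$retained, ])
    expect_true(all(again$retained))
})

test_that("the full filter stage rescues and filters gene trees", {
    st <- makeSpeciesTree(24, c(2, 2, 1), seed = 4)
    g <- simulateGeneTrees(st, 12, 0, seed = 5, missingFrac = 0.1,
                           minSpecies = 15, minForeground = 4)
    out <- ogFilterStage(g$trees, foregroundTips(st),
                         minSpecies = 15, minForeground = 4)
    expect_equal(nrow(out$report), 12)
    expect_true(all(out$report$n_species[out$report$retained] >= 15))
    expect_setequal(names(out$trees),
                    out$report$og_id[out$report$retained])
})
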