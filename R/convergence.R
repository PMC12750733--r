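## Convergent relative-evolutionary-rate scan. Each gene is scored by a
## pair-based statistic contrasting foreground (DUI) against background
## (SMI) relative rates, with permutation significance and the random /
## phylogenetic tagging control harness.

#' Relative tip rates of a gene tree against the species tree
#'
#' For every species shared between the two trees,
#' `r_s = log(d_s(gene) / d_s(species))` where `d_s` are root-to-tip path
#' distances on the shared (pruned) topology; the gene-wise median is
#' subtracted so that a gene's overall rate (which scales every branch)
#' drops out and only per-lineage deviations remain.
#'
#' @param geneTree a [TaggedTree-class]; its tips must be a subset of the
#'   species tree's.
#' @param speciesTree the reference [TaggedTree-class].
#' @return named numeric vector of centered log relative rates.
#' @export
relativeTipRates <- function(geneTree, speciesTree) {
    shared <- intersect(tipLabels(geneTree), tipLabels(speciesTree))
    if (length(shared) < 2) stop("fewer than 2 shared species")
    gt <- if (length(shared) < length(tipLabels(geneTree)))
        pruneTo(geneTree, shared) else geneTree
    st <- if (length(shared) < length(tipLabels(speciesTree)))
        pruneTo(speciesTree, shared) else speciesTree
    dg <- rootToTip(gt)[shared]
    ds <- rootToTip(st)[shared]
    if (any(ds <= 0))
        stop("degenerate reference: zero root-to-tip distance for ",
             names(ds)[ds <= 0][1])
    dg <- pmax(dg, 1e-8)       # guard a fully collapsed gene lineage
    r <- log(dg / ds)
    r - median(r)
}

# pair-weighted foreground-background rate contrast; weights down-weight
# phylogenetically redundant pairs (same species-tree MRCA)
.pairStatistic <- function(r, fgIdx, bgIdx, mrcaMat = NULL) {
    diff <- outer(r[fgIdx], r[bgIdx], "-")
    if (is.null(mrcaMat)) return(mean(diff))
    m <- mrcaMat[fgIdx, bgIdx, drop = FALSE]
    w <- 1 / tabulate(match(m, unique(as.vector(m))))[
        match(m, unique(as.vector(m)))]
    sum(w * diff) / sum(w)
}

# sizes of the maximal foreground clades on a phylo tree (fgIdx = tip
# indices), plus the clade candidate table used by the permutation sampler
.maximalCladeSizes <- function(tr, fgIdx) {
    ntip <- ape::Ntip(tr)
    nn <- ntip + tr$Nnode
    allFg <- logical(nn); allFg[fgIdx] <- TRUE
    post <- ape::reorder.phylo(tr, "postorder")$edge
    nChild <- tabulate(post[, 1L], nn)
    fgChild <- integer(nn)
    parent <- integer(nn)
    for (i in seq_len(nrow(post))) {
        p <- post[i, 1L]; ch <- post[i, 2L]
        parent[ch] <- p
        if (allFg[ch]) fgChild[p] <- fgChild[p] + 1L
        if (nChild[p] > 0L && fgChild[p] == nChild[p]) allFg[p] <- TRUE
    }
    maximal <- which(allFg & (parent == 0L | !allFg[pmax(parent, 1L)]))
    sizes <- vapply(maximal, function(nd)
        length(.descendantTips(tr, nd)), integer(1))
    sort(sizes, decreasing = TRUE)
}

# one random disjoint placement of monophyletic groups with the given
# size profile; NULL when the greedy draw fails
.drawCladeTagging <- function(cladeTips, cladeSizes, ntip, profile) {
    used <- logical(ntip)
    out <- integer(0)
    for (s in profile) {
        if (s == 1L) {
            free <- which(!used)
            if (!length(free)) return(NULL)
            pick <- free[sample.int(length(free), 1L)]
            used[pick] <- TRUE
            out <- c(out, pick)
        } else {
            ok <- which(cladeSizes == s)
            ok <- ok[vapply(ok, function(i) !any(used[cladeTips[[i]]]),
                            logical(1))]
            if (!length(ok)) return(NULL)
            pick <- cladeTips[[ok[sample.int(length(ok), 1L)]]]
            used[pick] <- TRUE
            out <- c(out, pick)
        }
    }
    out
}

#' Random clade-structured tagging of a tree
#'
#' Draws a random set of disjoint monophyletic groups with the given
#' clade-size profile among the tree's tips - the same placement scheme
#' the permutation null of [convergenceTest()] uses. Useful for
#' calibration simulations and tagging controls.
#'
#' @param tree a [TaggedTree-class].
#' @param cladeSizes integer size profile, e.g. `c(2, 2, 2, 2, 1, 1)`.
#' @param seed integer seed.
#' @return character vector of tagged tip labels.
#' @export
randomCladeTagging <- function(tree, cladeSizes, seed = 1) {
    set.seed(seed)
    tr <- asPhylo(tree)
    ntip <- ape::Ntip(tr)
    inner <- (ntip + 1L):(ntip + tr$Nnode)
    cladeTips <- lapply(inner, function(nd) .descendantTips(tr, nd))
    cladeSz <- lengths(cladeTips)
    keep <- cladeSz <= max(cladeSizes)
    profile <- sort(as.integer(cladeSizes), decreasing = TRUE)
    for (try in 1:50) {
        pf <- .drawCladeTagging(cladeTips[keep], cladeSz[keep], ntip,
                                profile)
        if (!is.null(pf)) return(sort(tr$tip.label[pf]))
    }
    stop("no disjoint monophyletic placement with profile ",
         paste(profile, collapse = ","))
}

#' Permutation test for convergent rate deviation in foreground species
#'
#' The statistic `T` averages `r_fg - r_bg` over all foreground x
#' background species pairs (relative rates from [relativeTipRates()]),
#' optionally down-weighting phylogenetically redundant pairs by
#' `1 / (number of pairs sharing the same species-tree MRCA)`. Negative `T`
#' means convergently constrained foreground lineages, positive means
#' accelerated. Significance comes from permutations that re-tag the gene
#' tree with random disjoint monophyletic groups matching the observed
#' foreground's clade-size profile (so a foreground of four species pairs
#' plus two singletons is compared against random placements of four
#' cherries plus two tips, keeping the permutation null faithful to the
#' clustered tagging; draws fall back to uniform tip sampling when no
#' placement exists): `p = (1 + #(|T*| >= |T|)) / (nPerm + 1)`.
#'
#' @param geneTree a [TaggedTree-class].
#' @param speciesTree the reference [TaggedTree-class].
#' @param foreground foreground tip set (default: the species tree's tags).
#' @param nPerm number of permutations (default 999).
#' @param pairWeighting `"mrca_depth"` (default) or `"uniform"`.
#' @param seed integer seed for the permutation draws.
#' @param cladeAware match the foreground clade-size profile in the
#'   permutation draws (default `TRUE`; `FALSE` gives plain size-preserving
#'   uniform draws).
#' @param permProfile optional integer clade-size profile to use for the
#'   permutation placements instead of the profile observed on the gene
#'   tree. Fixing the profile makes an observed tagging drawn by
#'   [randomCladeTagging()] with the same profile exactly exchangeable
#'   with the permutation draws (the observed profile can merge adjacent
#'   groups, which slightly over-clusters the recomputed null); used by
#'   calibration studies.
#' @return data.frame with `statistic`, `direction`, `p`, `nForeground`,
#'   `nBackground`, or `NULL` (with a message) when fewer than 2 foreground
#'   or background tips are present in the gene tree.
#' @export
convergenceTest <- function(geneTree, speciesTree,
                            foreground = foregroundTips(speciesTree),
                            nPerm = 999,
                            pairWeighting = c("mrca_depth", "uniform"),
                            seed = 1, cladeAware = TRUE,
                            permProfile = NULL) {
    pairWeighting <- match.arg(pairWeighting)
    ctx <- .convContext(geneTree, speciesTree, pairWeighting)
    .convTestCtx(ctx, foreground, nPerm = nPerm, seed = seed,
                 cladeAware = cladeAware, permProfile = permProfile)
}

# tagging-independent per-gene state: relative rates, MRCA matrix and the
# clade candidate table, shared across taggings by controlScan
.convContext <- function(geneTree, speciesTree, pairWeighting) {
    shared <- intersect(tipLabels(geneTree), tipLabels(speciesTree))
    gt <- if (length(shared) < length(tipLabels(geneTree)))
        pruneTo(geneTree, shared) else geneTree
    tr <- asPhylo(gt)
    r <- relativeTipRates(gt, speciesTree)[tr$tip.label]
    mrcaMat <- NULL
    if (pairWeighting == "mrca_depth") {
        st <- if (length(shared) < length(tipLabels(speciesTree)))
            pruneTo(speciesTree, shared) else speciesTree
        mrcaMat <- ape::mrca(asPhylo(st))[names(r), names(r)]
    }
    ntip <- ape::Ntip(tr)
    inner <- (ntip + 1L):(ntip + tr$Nnode)
    cladeTips <- lapply(inner, function(nd) .descendantTips(tr, nd))
    list(tr = tr, r = r, tips = names(r), mrcaMat = mrcaMat,
         cladeTips = cladeTips, cladeSizes = lengths(cladeTips))
}

.convTestCtx <- function(ctx, foreground, nPerm, seed, cladeAware = TRUE,
                         permProfile = NULL) {
    tips <- ctx$tips
    fg <- intersect(foreground, tips)
    bg <- setdiff(tips, foreground)
    if (length(fg) < 2 || length(bg) < 2) {
        message("gene skipped: needs >= 2 foreground and >= 2 background ",
                "tips (has ", length(fg), "/", length(bg), ")")
        return(NULL)
    }
    r <- ctx$r
    fgIdx <- match(fg, tips); bgIdx <- match(bg, tips)
    Tobs <- .pairStatistic(r, fgIdx, bgIdx, ctx$mrcaMat)
    set.seed(seed)
    n <- length(tips); k <- length(fgIdx)
    cladeTips <- cladeSizes <- profile <- NULL
    if (cladeAware) {
        profile <- if (!is.null(permProfile))
            sort(as.integer(permProfile), decreasing = TRUE)
        else .maximalCladeSizes(ctx$tr, fgIdx)
        if (max(profile) == 1L) {
            cladeAware <- FALSE   # uniform draws already match the profile
        } else {
            keep <- ctx$cladeSizes <= max(profile)
            cladeTips <- ctx$cladeTips[keep]
            cladeSizes <- ctx$cladeSizes[keep]
        }
    }
    exceed <- 0L
    for (b in seq_len(nPerm)) {
        pf <- NULL
        if (cladeAware)
            for (try in 1:10) {
                pf <- .drawCladeTagging(cladeTips, cladeSizes, n, profile)
                if (!is.null(pf)) break
            }
        if (is.null(pf)) pf <- sample.int(n, k)
        Tb <- .pairStatistic(r, pf, setdiff(seq_len(n), pf), ctx$mrcaMat)
        if (abs(Tb) >= abs(Tobs) - 1e-12) exceed <- exceed + 1L
    }
    data.frame(statistic = Tobs,
               direction = if (Tobs <= 0) "constrained" else "accelerated",
               p = (1 + exceed) / (nPerm + 1),
               nForeground = length(fgIdx), nBackground = length(bgIdx))
}

#' Scan a gene set for convergence
#'
#' @param geneTrees named list of [TaggedTree-class] gene trees.
#' @param speciesTree the reference tree.
#' @param ... passed to [convergenceTest()].
#' @param seed integer seed; per-gene seeds are derived deterministically.
#' @return data.frame with one row per scored gene (`gene_id`, `statistic`,
#'   `direction`, `p`, ...); skipped genes are absent.
#' @export
convergenceScan <- function(geneTrees, speciesTree, ..., seed = 1) {
    res <- lapply(seq_along(geneTrees), function(i)
        convergenceTest(geneTrees[[i]], speciesTree, ...,
                        seed = seed + i))
    keep <- !vapply(res, is.null, logical(1))
    out <- do.call(rbind, res[keep])
    if (is.null(out)) return(NULL)
    cbind(gene_id = names(geneTrees)[keep], out,
          stringsAsFactors = FALSE)
}

# nearest non-foreground relatives of each foreground clade, one tag per
# foreground tip, drawn by cophenetic proximity on the species tree
.phyloControlTags <- function(speciesTree, foreground) {
    st <- asPhylo(speciesTree)
    bg <- setdiff(st$tip.label, foreground)
    if (!length(bg)) return(NULL)
    D <- ape::cophenetic.phylo(st)
    tags <- character(0)
    for (f in foreground) {
        cand <- setdiff(bg, tags)
        if (!length(cand)) return(NULL)
        tags <- c(tags, cand[which.min(D[f, cand])])
    }
    sort(tags)
}

#' Random and phylogenetic tagging controls for the convergence scan
#'
#' Re-runs the permutation scan with (a) the true foreground tagging,
#' (b) `nRandom` taggings of `randomTagSize` background species drawn at
#' random, and (c) a phylogenetic control tagging the nearest background
#' relative of every foreground tip. For each run it reports the fraction
#' of genes with `p < alpha`, split by direction, and the rank of the true
#' run among the random runs (one-sided empirical p of seeing as extreme a
#' low-p fraction by chance).
#'
#' @param geneTrees named list of gene trees.
#' @param speciesTree the reference tree.
#' @param nRandom number of random taggings (default 50).
#' @param randomTagSize species per random tagging (default 10).
#' @param alpha significance level defining the low-p fraction
#'   (default 0.05).
#' @param nPerm permutations per test.
#' @param pairWeighting passed to [convergenceTest()].
#' @param seed integer seed.
#' @return list with `pValues` (genes x runs matrix; columns `true`,
#'   `random1..k`, `phylo`), `summary` (per-run low-p fractions by
#'   direction), `trueRank` and `rankP` (constrained direction), and the
#'   configuration used.
#' @export
controlScan <- function(geneTrees, speciesTree, nRandom = 50,
                        randomTagSize = 10, alpha = 0.05, nPerm = 199,
                        pairWeighting = "mrca_depth", seed = 1) {
    fg <- foregroundTips(speciesTree)
    bgPool <- setdiff(tipLabels(speciesTree), fg)
    if (nRandom > 0 && length(bgPool) < randomTagSize)
        stop("background pool too small for random taggings")
    set.seed(seed)
    taggings <- list(true = fg)
    for (b in seq_len(nRandom))
        taggings[[paste0("random", b)]] <- sample(bgPool, randomTagSize)
    phylo <- .phyloControlTags(speciesTree, fg)
    if (is.null(phylo))
        warning("phylogenetic control unavailable (no background ",
                "relatives); control skipped")
    else taggings$phylo <- phylo
    runs <- names(taggings)
    pv <- dirn <- matrix(NA_real_, length(geneTrees), length(taggings),
                         dimnames = list(names(geneTrees), runs))
    for (i in seq_along(geneTrees)) {
        ctx <- .convContext(geneTrees[[i]], speciesTree, pairWeighting)
        for (j in seq_along(taggings)) {
            res <- .convTestCtx(ctx, taggings[[j]], nPerm = nPerm,
                                seed = seed + 1000L * j + i)
            if (is.null(res)) next
            pv[i, j] <- res$p
            dirn[i, j] <- if (res$direction == "constrained") -1 else 1
        }
    }
    lowCon <- colMeans(pv < alpha & dirn < 0, na.rm = TRUE)
    lowAcc <- colMeans(pv < alpha & dirn > 0, na.rm = TRUE)
    summary <- data.frame(run = runs, lowP_constrained = lowCon,
                          lowP_accelerated = lowAcc,
                          lowP_total = lowCon + lowAcc,
                          stringsAsFactors = FALSE)
    rnd <- grep("^random", runs)
    trueRank <- rankP <- NA_real_
    if (length(rnd)) {
        trueRank <- 1 + sum(lowCon[rnd] >= lowCon["true"])
        rankP <- (1 + sum(lowCon[rnd] >= lowCon["true"])) /
            (length(rnd) + 1)
    }
    list(pValues = pv, direction = dirn, summary = summary,
         trueRank = trueRank, rankP = rankP,
         config = list(nRandom = nRandom, randomTagSize = randomTagSize,
                       alpha = alpha, nPerm = nPerm, seed = seed,
                       pairWeighting = pairWeighting,
                       phyloControl = !is.null(phylo)))
}
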