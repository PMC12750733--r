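## Synthetic-data generators. Every generator is a pure function of its
## parameters and seed and returns machine-readable truth labels so that
## downstream recovery can be scored. Defaults emulate the modeled design:
## 36 bivalve species in 3 subclasses with 6 independent DUI origins
## (10 foreground tips), 8 egg-pool samples in a 4-vs-4 sex-bias contrast.

#' Simulate a tagged species tree
#'
#' Birth-death shape (unit birth rate, no extinction), branch lengths
#' rescaled to a mean of 0.1 substitutions/site. Tips are partitioned into
#' three monophyletic subclasses (the tree is assembled from three subclass
#' subtrees), and the requested number of disjoint monophyletic foreground
#' clades is tagged, emulating independent origins of doubly uniparental
#' inheritance.
#'
#' @param nSpecies total number of tips (default 36).
#' @param cladeSizes integer vector, one entry per foreground clade
#'   (default `c(2, 2, 2, 2, 1, 1)`: six DUI origins, ten DUI tips).
#' @param seed integer seed.
#' @param meanBranch target mean branch length after rescaling.
#' @return a [TaggedTree-class] with foreground tags and subclass labels.
#' @examples
#' tt <- makeSpeciesTree(36, c(2, 2, 2, 2, 1, 1), seed = 1)
#' length(foregroundTips(tt))
#' @export
makeSpeciesTree <- function(nSpecies = 36,
                            cladeSizes = c(2, 2, 2, 2, 1, 1),
                            seed = 1, meanBranch = 0.1) {
    nClades <- length(cladeSizes)
    stopifnot(nClades >= 1, all(cladeSizes >= 1))
    if (nSpecies < sum(cladeSizes) + nClades)
        stop("impossible clade placement: need at least ",
             sum(cladeSizes) + nClades, " species for ", nClades,
             " foreground clades of total size ", sum(cladeSizes))
    set.seed(seed)
    nSub <- c(ceiling(nSpecies * 0.4), ceiling(nSpecies * 0.3), 0)
    nSub[3] <- nSpecies - sum(nSub[1:2])
    if (any(nSub < 2)) nSub <- c(nSpecies - 4, 2, 2)
    if (any(nSub < 2)) stop("need at least 6 species for three subclasses")
    subTree <- lapply(nSub, function(n) ape::rphylo(n, birth = 1, death = 0))
    labs <- sprintf("sp%02d", seq_len(nSpecies))
    off <- c(0, cumsum(nSub))
    nwk <- character(3)
    for (k in 1:3) {
        subTree[[k]]$tip.label <- labs[(off[k] + 1):(off[k] + nSub[k])]
        nwk[k] <- sub(";$", "", ape::write.tree(subTree[[k]]))
    }
    tr <- ape::read.tree(text = sprintf("((%s:0.6,%s:0.6):0.4,%s:1.0);",
                                        nwk[1], nwk[2], nwk[3]))
    tr$edge.length <- tr$edge.length * meanBranch / mean(tr$edge.length)
    subclass <- setNames(rep(c("A", "B", "C"), nSub)[
        match(tr$tip.label, labs)], tr$tip.label)
    fg <- .placeForegroundClades(tr, cladeSizes)
    if (is.null(fg))
        stop("impossible clade placement: no disjoint monophyletic groups ",
             "of sizes ", paste(cladeSizes, collapse = ","),
             " found; change cladeSizes or nSpecies")
    taggedTree(tr, foreground = fg, subclass = subclass)
}

# randomized greedy search for disjoint monophyletic foreground groups
.placeForegroundClades <- function(tr, cladeSizes) {
    ntip <- ape::Ntip(tr)
    cladeTips <- lapply((ntip + 1):(ntip + tr$Nnode), function(nd)
        .descendantTips(tr, nd))
    for (attempt in 1:200) {
        used <- logical(ntip)
        chosen <- list()
        ok <- TRUE
        for (s in sort(cladeSizes, decreasing = TRUE)) {
            if (s == 1L) {
                free <- which(!used)
                # a singleton must not sit inside an already-chosen clade
                if (!length(free)) { ok <- FALSE; break }
                pick <- sample(free, 1L)
                used[pick] <- TRUE
                chosen[[length(chosen) + 1L]] <- pick
            } else {
                cand <- which(vapply(cladeTips, function(tp)
                    length(tp) == s && !any(used[tp]), logical(1)))
                if (!length(cand)) { ok <- FALSE; break }
                pick <- cladeTips[[sample(rep(cand, 2L), 1L)]]
                used[pick] <- TRUE
                chosen[[length(chosen) + 1L]] <- pick
            }
        }
        # require at least as many untagged tips as clades (background pool)
        if (ok && sum(!used) >= length(cladeSizes))
            return(sort(tr$tip.label[unlist(chosen)]))
    }
    NULL
}

#' Shared branch-rate deviations for rate-covariation simulations
#'
#' One lognormal multiplier per species-tree branch; feeding the same
#' vector to [simulateMitoTree()] and (via `ercDeviations`) to
#' [simulateGeneTrees()] plants a covarying-rate signal.
#'
#' @param speciesTree a [TaggedTree-class].
#' @param sd standard deviation of the log multiplier (default 0.6).
#' @param seed integer seed.
#' @return numeric vector, one multiplier per edge of the species tree.
#' @export
simulateRateDeviations <- function(speciesTree, sd = 0.6, seed = 1) {
    set.seed(seed)
    nE <- nrow(asPhylo(speciesTree)$edge)
    rlnorm(nE, meanlog = -sd^2 / 2, sdlog = sd)
}

#' Simulate a mitochondrial concatenate tree
#'
#' Species-tree topology with branch lengths multiplied by the shared
#' rate-deviation vector plus independent lognormal noise.
#'
#' @param speciesTree a [TaggedTree-class].
#' @param deviations per-branch multipliers from [simulateRateDeviations()].
#' @param noiseSd lognormal sd of the independent branch noise.
#' @param seed integer seed.
#' @param scale global rate multiplier (mitochondrial trees are typically
#'   faster; default 2).
#' @return a [TaggedTree-class].
#' @export
simulateMitoTree <- function(speciesTree, deviations, noiseSd = 0.2,
                             seed = 1, scale = 2) {
    set.seed(seed)
    tr <- asPhylo(speciesTree)
    stopifnot(length(deviations) == nrow(tr$edge))
    eps <- rlnorm(nrow(tr$edge), -noiseSd^2 / 2, noiseSd)
    tr$edge.length <- tr$edge.length * scale * deviations * eps
    taggedTree(tr, foreground = foregroundTips(speciesTree),
               subclass = subclassLabels(speciesTree))
}

#' Simulate gene trees with planted convergent rate shifts
#'
#' Each gene tree carries the species-tree topology restricted to its
#' sampled taxa. Branch lengths are
#' `b * g_gene * eps_e * m_e (* eta_e for rate-covariation-linked genes)`
#' where `g_gene` is a lognormal gene-wide rate, `eps_e` independent
#' lognormal branch noise, and `m_e` equals `rateMultiplier` on foreground
#' branches of "constrained" genes (`1/rateMultiplier` for "accelerated",
#' 1 elsewhere). Missing taxa are dropped uniformly at random; when
#' `filterSafe` is `TRUE` the draw is repeated until the gene passes the
#' downstream orthogroup filters.
#'
#' @param speciesTree a [TaggedTree-class].
#' @param nGenes number of genes.
#' @param constrainedFrac fraction of genes with convergent constrained
#'   evolution.
#' @param rateMultiplier foreground branch multiplier for constrained genes
#'   (< 1 slows them down); must be > 0.
#' @param lognormalNoiseSd sd of the log branch noise.
#' @param missingFrac per-tip drop probability.
#' @param seed integer seed.
#' @param acceleratedFrac fraction of genes with convergent accelerated
#'   evolution (default 0).
#' @param ercFrac fraction of genes sharing `ercDeviations` with the
#'   mitochondrial tree (default 0).
#' @param ercDeviations per-branch multipliers from
#'   [simulateRateDeviations()]; required when `ercFrac > 0`.
#' @param ercConstrainedWeight relative weight with which constrained genes
#'   attract the rate-covariation linkage (default 1 = uniform; larger
#'   values plant the mito-association among the convergently constrained
#'   genes).
#' @param ercDamping exponent applied to `ercDeviations` on linked gene
#'   trees (default 0.5): rate covariation needs correlated, not
#'   equal-amplitude, branch deviations, and full-amplitude mitochondrial
#'   deviations would drown the lineage-rate signals of the genes that
#'   carry them.
#' @param geneRateSd sd of the lognormal gene-wide rate `g_gene`.
#' @param filterSafe resample tip drops until the gene keeps at least
#'   `minSpecies` tips and `minForeground` foreground tips.
#' @param minSpecies,minForeground the downstream retention thresholds
#'   (defaults 15 and 4).
#' @return list with `trees` (named list of [TaggedTree-class]) and `truth`
#'   (data.frame: `gene_id`, `convergence_class`, `is_erc_linked`).
#' @export
simulateGeneTrees <- function(speciesTree, nGenes, constrainedFrac,
                              rateMultiplier = 0.3, lognormalNoiseSd = 0.2,
                              missingFrac = 0.1, seed = 1,
                              acceleratedFrac = 0, ercFrac = 0,
                              ercDeviations = NULL,
                              ercConstrainedWeight = 1, ercDamping = 0.5,
                              geneRateSd = 0.5,
                              filterSafe = TRUE, minSpecies = 15,
                              minForeground = 4) {
    stopifnot(constrainedFrac >= 0, constrainedFrac <= 1,
              acceleratedFrac >= 0, constrainedFrac + acceleratedFrac <= 1)
    if (rateMultiplier <= 0) stop("rateMultiplier must be > 0")
    if (ercFrac > 0 && is.null(ercDeviations))
        stop("ercDeviations required when ercFrac > 0")
    set.seed(seed)
    tr <- asPhylo(speciesTree)
    nE <- nrow(tr$edge)
    ntip <- ape::Ntip(tr)
    fgEdge <- foregroundEdges(speciesTree)
    nCon <- round(nGenes * constrainedFrac)
    nAcc <- round(nGenes * acceleratedFrac)
    cls <- sample(rep(c("constrained", "accelerated", "null"),
                      c(nCon, nAcc, nGenes - nCon - nAcc)))
    ercLinked <- logical(nGenes)
    if (ercFrac > 0) {
        w <- ifelse(cls == "constrained", ercConstrainedWeight, 1)
        ercLinked[sample.int(nGenes, round(nGenes * ercFrac),
                             prob = w / sum(w))] <- TRUE
    }
    ids <- sprintf("g%04d", seq_len(nGenes))
    fgTips <- foregroundTips(speciesTree)
    minSpecies <- min(minSpecies, ntip)
    minForeground <- min(minForeground, length(fgTips))
    trees <- vector("list", nGenes)
    for (g in seq_len(nGenes)) {
        gt <- tr
        m <- rep(1, nE)
        if (cls[g] == "constrained") m[fgEdge] <- rateMultiplier
        if (cls[g] == "accelerated") m[fgEdge] <- 1 / rateMultiplier
        eta <- if (ercLinked[g]) ercDeviations^ercDamping else rep(1, nE)
        gRate <- rlnorm(1, 0, geneRateSd)
        eps <- rlnorm(nE, -lognormalNoiseSd^2 / 2, lognormalNoiseSd)
        gt$edge.length <- gt$edge.length * gRate * eps * m * eta
        keep <- tr$tip.label
        if (missingFrac > 0) {
            for (try in 1:100) {
                drop <- runif(ntip) < missingFrac
                cand <- tr$tip.label[!drop]
                if (!filterSafe ||
                    (length(cand) >= minSpecies &&
                     sum(cand %in% fgTips) >= minForeground)) {
                    keep <- cand; break
                }
            }
        }
        tg <- taggedTree(gt, foreground = fgTips,
                         subclass = subclassLabels(speciesTree))
        trees[[g]] <- if (length(keep) < ntip) pruneTo(tg, keep) else tg
    }
    names(trees) <- ids
    list(trees = trees,
         truth = data.frame(gene_id = ids, convergence_class = cls,
                            is_erc_linked = ercLinked,
                            stringsAsFactors = FALSE))
}

#' Simulate a codon alignment under a branch-specific GY94 model
#'
#' Sites evolve independently along the tree under the GY94 generator (see
#' [gy94RateMatrix()]); branches of the foreground clades use `omegaFg`,
#' all others `omegaBg`, with the generator scaled so background branch
#' lengths are in expected substitutions per codon. The root state is drawn
#' from `freqs`.
#'
#' @param tree a [TaggedTree-class] with branch lengths.
#' @param nCodons number of codon sites.
#' @param omegaBg,omegaFg background and foreground dN/dS.
#' @param kappa transition/transversion ratio.
#' @param freqs codon frequencies over [senseCodons()] (default uniform).
#' @param seed integer seed.
#' @param stem passed to [foregroundEdges()].
#' @return a [CodonAlignment-class] with one row per tip.
#' @export
simulateCodonAlignment <- function(tree, nCodons, omegaBg, omegaFg = omegaBg,
                                   kappa = 2, freqs = rep(1 / 61, 61),
                                   seed = 1, stem = "include") {
    stopifnot(is(tree, "TaggedTree"), nCodons >= 1)
    tr <- asPhylo(tree)
    if (is.null(tr$edge.length)) stop("tree has no branch lengths")
    if (abs(sum(freqs) - 1) > 1e-8) stop("freqs must sum to 1")
    set.seed(seed)
    mu <- .gy94Rate(kappa, omegaBg, freqs)
    eigBg <- .reversibleEigen(gy94RateMatrix(kappa, omegaBg, freqs,
                                             normalize = mu), freqs)
    eigFg <- if (omegaFg != omegaBg)
        .reversibleEigen(gy94RateMatrix(kappa, omegaFg, freqs,
                                        normalize = mu), freqs)
    else eigBg
    fgEdge <- foregroundEdges(tree, stem = stem)
    isFg <- logical(nrow(tr$edge)); isFg[fgEdge] <- TRUE
    ntip <- ape::Ntip(tr)
    nn <- ntip + tr$Nnode
    states <- matrix(0L, nn, nCodons)
    states[ntip + 1L, ] <- sample.int(61, nCodons, replace = TRUE,
                                      prob = freqs)
    post <- ape::reorder.phylo(tr, "postorder")
    ord <- rev(seq_len(nrow(post$edge)))   # preorder
    pkey <- paste(post$edge[, 1], post$edge[, 2])
    okey <- paste(tr$edge[, 1], tr$edge[, 2])
    postFg <- isFg[match(pkey, okey)]
    for (i in ord) {
        par <- post$edge[i, 1L]; ch <- post$edge[i, 2L]
        eig <- if (postFg[i]) eigFg else eigBg
        P <- .transitionProb(eig, post$edge.length[i])
        P <- P / rowSums(P)
        ps <- states[par, ]
        out <- integer(nCodons)
        for (st in unique(ps)) {
            j <- which(ps == st)
            out[j] <- sample.int(61, length(j), replace = TRUE,
                                 prob = P[st, ])
        }
        states[ch, ] <- out
    }
    codons <- states[seq_len(ntip), , drop = FALSE]
    rownames(codons) <- tr$tip.label
    new("CodonAlignment", codons = codons)
}

#' Simulate a negative-binomial count matrix with sex-ratio-linked features
#'
#' Counts are negative binomial with mean
#' `mu_fs = L_s * q_f * 2^(lfc_f * x_s)` where `L_s` is the library size,
#' `q_f` the relative abundance, `x_s` the centered per-sample offspring
#' sex ratio, and `lfc_f` nonzero only for the planted differentially
#' deposited features.
#'
#' @param nFeatures,nSamples dimensions (defaults emulate a deep
#'   rRNA-depleted egg-pool experiment: 15826 features, 8 samples).
#' @param groupLabels per-sample bias labels (two levels; default 4
#'   `female_biased` then 4 `male_biased`).
#' @param sexRatios per-sample offspring sex ratios in `[0,1]` (fraction of
#'   male-developing embryos; defaults 0.1-0.25 for female-biased and
#'   0.75-0.9 for male-biased pools).
#' @param deFrac fraction of features with planted signal.
#' @param lfcMean mean |log2 fold change per unit sex ratio| of planted
#'   features.
#' @param dispersion negative-binomial dispersion (`size = 1/dispersion`).
#' @param libSizeRange range the library sizes are drawn from.
#' @param seed integer seed.
#' @return list with `counts` (an [EggCounts-class]) and `truth`
#'   (data.frame: `feature_id`, `is_de`, `de_lfc`).
#' @export
simulateCounts <- function(nFeatures = 15826, nSamples = 8,
                           groupLabels = rep(c("female_biased",
                                               "male_biased"), each = 4),
                           sexRatios = NULL, deFrac = 0.016, lfcMean = 2,
                           dispersion = 0.1,
                           libSizeRange = c(8e6, 1.2e7), seed = 1) {
    if (dispersion <= 0) stop("dispersion must be > 0")
    stopifnot(length(groupLabels) == nSamples)
    set.seed(seed)
    if (is.null(sexRatios)) {
        # high male fraction for the male-biased level, low for the other
        maleLevel <- if ("male_biased" %in% groupLabels) "male_biased"
                     else unique(groupLabels)[2]
        isMale <- groupLabels == maleLevel
        sexRatios <- ifelse(isMale, runif(nSamples, 0.75, 0.90),
                            runif(nSamples, 0.10, 0.25))
    }
    stopifnot(length(sexRatios) == nSamples,
              all(sexRatios >= 0 & sexRatios <= 1))
    q <- rlnorm(nFeatures, 0, 1.5)
    q <- q / sum(q)
    nDe <- round(nFeatures * deFrac)
    lfc <- numeric(nFeatures)
    if (nDe > 0) {
        deIdx <- sample.int(nFeatures, nDe)
        lfc[deIdx] <- sample(c(-1, 1), nDe, replace = TRUE) *
            pmax(rnorm(nDe, lfcMean, 0.25), lfcMean / 2)
    }
    L <- round(runif(nSamples, libSizeRange[1], libSizeRange[2]))
    x <- sexRatios - mean(sexRatios)
    mu <- outer(q, L) * 2^(lfc %o% x)
    cnt <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                  nFeatures, nSamples)
    ids <- sprintf("feat%05d", seq_len(nFeatures))
    dimnames(cnt) <- list(ids, sprintf("s%02d", seq_len(nSamples)))
    list(counts = eggCounts(cnt, sexRatio = sexRatios, bias = groupLabels),
         truth = data.frame(feature_id = ids, is_de = lfc != 0,
                            de_lfc = lfc, stringsAsFactors = FALSE))
}

#' Simulate a scored interactome with a planted cross-set module
#'
#' Erdos-Renyi background over all node pairs; pairs with one endpoint in
#' `setA` and the other in `setB` are wired with the planted probability.
#' All retained edges carry a confidence score at or above `minScore`.
#'
#' @param nNodes number of nodes (ids `n001`, ...).
#' @param backgroundEdgeProb background edge probability.
#' @param setA,setB node-id vectors (overlap allowed); labelled
#'   `DE_up_female` and `CE` respectively.
#' @param plantedEdgeProb probability of an A-B edge (must be >=
#'   `backgroundEdgeProb`).
#' @param seed integer seed.
#' @param minScore minimum confidence score of retained edges.
#' @return list with `graph` (an [Interactome-class]) and `truth`
#'   (data.frame: `node`, `planted_module_member`).
#' @export
simulateInteractome <- function(nNodes, backgroundEdgeProb, setA, setB,
                                plantedEdgeProb = backgroundEdgeProb,
                                seed = 1, minScore = 0.400) {
    if (backgroundEdgeProb < 0 || backgroundEdgeProb > 1 ||
        plantedEdgeProb < 0 || plantedEdgeProb > 1)
        stop("edge probabilities must be in [0, 1]")
    if (plantedEdgeProb < backgroundEdgeProb)
        stop("plantedEdgeProb must be >= backgroundEdgeProb")
    set.seed(seed)
    nodes <- sprintf("n%03d", seq_len(nNodes))
    stopifnot(all(setA %in% nodes), all(setB %in% nodes))
    pr <- utils::combn(nNodes, 2)
    inA <- nodes %in% setA; inB <- nodes %in% setB
    cross <- (inA[pr[1, ]] & inB[pr[2, ]]) | (inB[pr[1, ]] & inA[pr[2, ]])
    p <- ifelse(cross, plantedEdgeProb, backgroundEdgeProb)
    on <- runif(ncol(pr)) < p
    edges <- data.frame(node_a = nodes[pr[1, on]], node_b = nodes[pr[2, on]],
                        score = runif(sum(on), minScore, 1),
                        stringsAsFactors = FALSE)
    labels <- setNames(rep("other", nNodes), nodes)
    labels[inA] <- "DE_up_female"
    labels[inB] <- "CE"
    labels[inA & inB] <- "CE"
    list(graph = interactome(edges, labels = labels, nodes = nodes,
                             minScore = minScore),
         truth = data.frame(node = nodes,
                            planted_module_member = inA | inB,
                            stringsAsFactors = FALSE))
}

#' Simulate synthetic gene intervals on a set of scaffolds
#'
#' @param nGenes number of genes.
#' @param focalGenes character vector of gene ids to flag as focal (DE), or
#'   an integer count drawn at random.
#' @param seed integer seed.
#' @param meanWidth mean gene width in bp.
#' @return data.frame of gene intervals (0-based half-open) with a `focal`
#'   flag, as produced by [readGeneIntervals()].
#' @export
simulateGeneIntervals <- function(nGenes, focalGenes = 0, seed = 1,
                                  meanWidth = 3000) {
    set.seed(seed)
    ids <- sprintf("gene%04d", seq_len(nGenes))
    if (is.numeric(focalGenes) && length(focalGenes) == 1L)
        focalGenes <- sample(ids, focalGenes)
    widths <- pmax(300L, as.integer(rgamma(nGenes, shape = 3,
                                           scale = meanWidth / 3)))
    gap <- as.integer(runif(nGenes, 500, 5000))
    scaf <- sprintf("scaf%02d", 1 + (seq_len(nGenes) - 1) %/% 50)
    start <- integer(nGenes)
    pos <- 0L
    for (i in seq_len(nGenes)) {
        if (i > 1 && scaf[i] != scaf[i - 1]) pos <- 0L
        start[i] <- pos + gap[i]
        pos <- start[i] + widths[i]
    }
    data.frame(seqid = scaf, start = start, end = start + widths,
               strand = sample(c("+", "-"), nGenes, replace = TRUE),
               gene_id = ids, focal = ids %in% focalGenes,
               stringsAsFactors = FALSE)
}

#' Simulate a similarity-hit table with planted focal-gene bias
#'
#' Hits from each simulated lncRNA are placed inside genes with probability
#' proportional to gene width, multiplied by `focalGeneBias` for focal
#' (DE-flagged) genes. Identity, alignment length and query coverage are
#' drawn so that a configurable fraction of hits passes the retention
#' filters (see [filterHits()]).
#'
#' @param geneIntervals data.frame from [simulateGeneIntervals()] or
#'   [readGeneIntervals()].
#' @param nLncrnas number of query lncRNAs.
#' @param hitsPerLncrna hits per query.
#' @param focalGeneBias multiplier (>= 1) on placement probability into
#'   focal genes.
#' @param seed integer seed.
#' @param passFraction fraction of hits drawn to pass the filters.
#' @return list with `hits` (data.frame of hit records) and `truth`
#'   (data.frame: `query`, `host_gene`, `host_focal`).
#' @export
simulateHitTable <- function(geneIntervals, nLncrnas, hitsPerLncrna,
                             focalGeneBias = 1, seed = 1,
                             passFraction = 1) {
    if (nrow(geneIntervals) == 0) stop("empty gene interval set")
    if (focalGeneBias < 1) stop("focalGeneBias must be >= 1")
    set.seed(seed)
    w <- (geneIntervals$end - geneIntervals$start) *
        ifelse(geneIntervals$focal, focalGeneBias, 1)
    nHit <- nLncrnas * hitsPerLncrna
    gi <- sample.int(nrow(geneIntervals), nHit, replace = TRUE,
                     prob = w / sum(w))
    qid <- rep(sprintf("lnc%03d", seq_len(nLncrnas)), each = hitsPerLncrna)
    pass <- runif(nHit) < passFraction
    width <- geneIntervals$end[gi] - geneIntervals$start[gi]
    alnLen <- ifelse(pass,
                     pmin(as.integer(runif(nHit, 120, 300)), width),
                     pmin(as.integer(runif(nHit, 40, 100)), width))
    alnLen <- pmax(alnLen, 20L)
    start <- geneIntervals$start[gi] +
        floor(runif(nHit) * pmax(width - alnLen, 1))
    ident <- ifelse(pass, runif(nHit, 91, 99.9), runif(nHit, 70, 89.9))
    cov <- ifelse(pass, runif(nHit, 0.55, 0.95), runif(nHit, 0.1, 0.45))
    hits <- data.frame(query = qid, subject = geneIntervals$seqid[gi],
                       start = as.integer(start),
                       end = as.integer(start + alnLen),
                       strand = sample(c("+", "-"), nHit, replace = TRUE),
                       identity = ident, alnLength = alnLen,
                       coverage = cov, stringsAsFactors = FALSE)
    list(hits = hits,
         truth = data.frame(query = qid,
                            host_gene = geneIntervals$gene_id[gi],
                            host_focal = geneIntervals$focal[gi],
                            passes_filters = pass & alnLen > 100,
                            stringsAsFactors = FALSE))
}
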