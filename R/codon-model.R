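## GY94-style codon substitution machinery over the 61 sense codons of the
## standard genetic code. The generator is built in R; the per-site pruning
## likelihood runs in C++ (src/pruning.cpp).

.codonEnv <- new.env(parent = emptyenv())

#' The 61 sense codons of the standard genetic code
#'
#' Codons are ordered alphabetically (A < C < G < T) so that indices are
#' stable across sessions; the three stop codons (TAA, TAG, TGA) are
#' excluded.
#'
#' @return character vector of length 61.
#' @export
senseCodons <- function() .codonData()$codons

# memoized code tables: codons, encoded amino acids, and the single-step
# transition / nonsynonymous masks of the GY94 parametrization
.codonData <- function() {
    if (!is.null(.codonEnv$data)) return(.codonEnv$data)
    gc <- Biostrings::GENETIC_CODE
    codons <- sort(names(gc)[gc != "*"])
    aa <- unname(gc[codons])
    n <- length(codons)
    mat <- do.call(rbind, strsplit(codons, ""))
    diffPos <- matrix(0L, n, n)
    isTi <- matrix(FALSE, n, n)
    for (p in 1:3) {
        d <- outer(mat[, p], mat[, p], "!=")
        diffPos <- diffPos + d
        purine <- mat[, p] %in% c("A", "G")
        isTi <- isTi | (d & outer(purine, purine, "=="))
    }
    single <- diffPos == 1L
    nonsyn <- outer(aa, aa, "!=")
    .codonEnv$data <- list(codons = codons, aa = aa, single = single,
                           isTi = isTi & single, nonsyn = nonsyn)
    .codonEnv$data
}

#' GY94 instantaneous rate matrix
#'
#' Goldman-Yang codon rate matrix for one branch class:
#' `q_ij = pi_j * kappa^[transition] * omega^[nonsynonymous]` for codon
#' pairs differing at exactly one position (zero otherwise, and stop codons
#' are outside the state space); the diagonal makes rows sum to zero.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega nonsynonymous/synonymous rate ratio dN/dS (>= 0).
#' @param freqs equilibrium codon frequencies over [senseCodons()] (sum 1).
#' @param normalize if `TRUE` (default) scale the matrix so the expected
#'   number of substitutions per unit branch length is 1; pass
#'   `normalize = FALSE` (or a positive scalar to divide by) to keep several
#'   branch classes on one common scale (see [codonLoglik()]).
#' @return 61 x 61 rate matrix with `dimnames` the sense codons.
#' @export
gy94RateMatrix <- function(kappa, omega, freqs, normalize = TRUE) {
    stopifnot(kappa > 0, omega >= 0, length(freqs) == 61L)
    if (abs(sum(freqs) - 1) > 1e-8) stop("codon frequencies must sum to 1")
    cd <- .codonData()
    Q <- matrix(0, 61, 61, dimnames = list(cd$codons, cd$codons))
    Q[cd$single] <- rep(freqs, each = 61)[cd$single]
    Q[cd$isTi] <- Q[cd$isTi] * kappa
    Q[cd$single & cd$nonsyn] <- Q[cd$single & cd$nonsyn] * omega
    diag(Q) <- -rowSums(Q)
    if (isTRUE(normalize)) {
        mu <- -sum(freqs * diag(Q))
        if (mu > 0) Q <- Q / mu
    } else if (is.numeric(normalize) && normalize > 0) {
        Q <- Q / normalize
    }
    Q
}

# substitution rate (expected substitutions per unit time) of an
# unnormalized GY94 generator
.gy94Rate <- function(kappa, omega, freqs) {
    Q <- gy94RateMatrix(kappa, omega, freqs, normalize = FALSE)
    -sum(freqs * diag(Q))
}

# eigen-decomposition of a reversible generator for fast P(t):
# P(t) = A diag(exp(lambda t)) B with A = D^-1/2 U, B = U' D^1/2
.reversibleEigen <- function(Q, freqs) {
    sp <- sqrt(freqs)
    B <- Q * (sp %o% (1 / sp))
    B <- (B + t(B)) / 2            # symmetrize against rounding
    e <- eigen(B, symmetric = TRUE)
    list(values = e$values, A = e$vectors / sp, B = t(e$vectors * sp))
}

.transitionProb <- function(eig, t) {
    P <- eig$A %*% (exp(eig$values * t) * eig$B)
    P[P < 0] <- 0
    P
}

#' Empirical codon frequencies from an alignment
#'
#' @param alignment a [CodonAlignment-class].
#' @param method `"F1x4"` (product of overall nucleotide frequencies,
#'   default), `"F3x4"` (position-specific nucleotide frequencies), or
#'   `"uniform"`.
#' @return numeric vector of length 61 summing to 1.
#' @export
codonFrequencies <- function(alignment,
                             method = c("F1x4", "F3x4", "uniform")) {
    method <- match.arg(method)
    cd <- .codonData()
    if (method == "uniform") return(rep(1 / 61, 61))
    idx <- alignment@codons
    idx <- idx[idx > 0]
    if (!length(idx)) return(rep(1 / 61, 61))
    codonCount <- tabulate(idx, 61)
    mat <- do.call(rbind, strsplit(cd$codons, ""))
    nuc <- c("A", "C", "G", "T")
    if (method == "F1x4") {
        cnt <- setNames(numeric(4), nuc)
        for (p in 1:3)
            cnt <- cnt + vapply(nuc, function(b)
                sum(codonCount[mat[, p] == b]), numeric(1))
        f <- cnt / sum(cnt)
        freqs <- f[mat[, 1]] * f[mat[, 2]] * f[mat[, 3]]
    } else {
        f <- sapply(1:3, function(p) {
            cnt <- vapply(nuc, function(b)
                sum(codonCount[mat[, p] == b]), numeric(1))
            cnt / sum(cnt)
        })
        freqs <- f[, 1][mat[, 1]] * f[, 2][mat[, 2]] * f[, 3][mat[, 3]]
    }
    freqs <- pmax(as.numeric(freqs), 1e-10)
    freqs / sum(freqs)
}

# compress alignment columns into unique site patterns on the tree's tip
# ordering; returns integer matrix (tips x patterns) and weights
.sitePatterns <- function(alignment, tr) {
    idx <- alignment@codons
    miss <- setdiff(tr$tip.label, rownames(idx))
    if (length(miss))
        stop("alignment lacks tree tips: ", paste(miss, collapse = ", "))
    idx <- idx[tr$tip.label, , drop = FALSE]
    key <- apply(idx, 2, paste, collapse = ",")
    uk <- unique(key)
    m <- match(key, uk)
    list(patterns = idx[, match(uk, key), drop = FALSE],
         weights = as.numeric(tabulate(m, length(uk))))
}

#' Codon-alignment log-likelihood under a two-class GY94 branch model
#'
#' Felsenstein pruning over compressed site patterns, with per-branch
#' transition matrices `exp(Q_c t)` where the class `c` of a branch is
#' foreground (its own dN/dS) or background. Both generators share one
#' scale: the expected number of substitutions per unit branch length is 1
#' under the background class, so branch lengths keep their input units.
#'
#' @param alignment a [CodonAlignment-class]; tips must cover the tree.
#' @param tree a [TaggedTree-class] with branch lengths; its foreground tags
#'   define the foreground branch class via [foregroundEdges()].
#' @param kappa transition/transversion ratio.
#' @param omegaBg,omegaFg dN/dS of the background and foreground classes
#'   (`omegaFg` defaults to `omegaBg`, collapsing to the one-ratio model).
#' @param freqs codon frequencies (default F1x4 from the alignment).
#' @param scale global multiplier applied to all branch lengths.
#' @param stem passed to [foregroundEdges()].
#' @return log-likelihood (numeric scalar).
#' @export
codonLoglik <- function(alignment, tree, kappa, omegaBg,
                        omegaFg = omegaBg, freqs = NULL, scale = 1,
                        stem = "include") {
    stopifnot(is(alignment, "CodonAlignment"), is(tree, "TaggedTree"))
    if (is.null(freqs)) freqs <- codonFrequencies(alignment)
    ctx <- .likContext(alignment, tree, freqs, stem = stem)
    .ctxLoglik(ctx, kappa, omegaBg, omegaFg, scale)
}

# everything that does not depend on the model parameters: postorder
# edges, branch classes, compressed site patterns
.likContext <- function(alignment, tree, freqs, stem = "include") {
    tr <- tree@tree
    if (is.null(tr$edge.length)) stop("tree has no branch lengths")
    sp <- .sitePatterns(alignment, tr)
    if (ape::Ntip(tr) == 1L)
        return(list(singleTip = TRUE, sp = sp, freqs = freqs))
    fgEdge <- foregroundEdges(tree, stem = stem)
    post <- ape::reorder.phylo(tr, "postorder")
    edgeClassFg <- logical(nrow(tr$edge))
    edgeClassFg[fgEdge] <- TRUE
    pkey <- paste(post$edge[, 1], post$edge[, 2])
    okey <- paste(tr$edge[, 1], tr$edge[, 2])
    list(singleTip = FALSE, edges = post$edge,
         lengths = post$edge.length,
         classFg = as.integer(edgeClassFg[match(pkey, okey)]),
         sp = sp, freqs = freqs, nnode = tr$Nnode)
}

.ctxLoglik <- function(ctx, kappa, omegaBg, omegaFg = omegaBg,
                       scale = 1) {
    freqs <- ctx$freqs
    if (ctx$singleTip)
        return(sum(ctx$sp$weights *
                   log(ifelse(ctx$sp$patterns[1L, ] > 0,
                              freqs[pmax(ctx$sp$patterns[1L, ], 1L)], 1))))
    mu <- .gy94Rate(kappa, omegaBg, freqs)
    eigBg <- .reversibleEigen(gy94RateMatrix(kappa, omegaBg, freqs,
                                             normalize = mu), freqs)
    eigFg <- if (any(ctx$classFg == 1L) && omegaFg != omegaBg)
        .reversibleEigen(gy94RateMatrix(kappa, omegaFg, freqs,
                                        normalize = mu), freqs)
    else eigBg
    pruneLoglikC(ctx$edges, ctx$lengths * scale, ctx$classFg,
                 eigBg$A, eigBg$values, eigBg$B,
                 eigFg$A, eigFg$values, eigFg$B,
                 ctx$sp$patterns, ctx$sp$weights, freqs, ctx$nnode)
}

#' One-ratio versus two-ratio branch-model likelihood ratio test
#'
#' Fits a null model (one dN/dS shared by all branches) and a nested
#' alternative in which branches of the foreground (DUI) clades carry their
#' own dN/dS, by bounded numerical maximization over (kappa, omega(s),
#' global branch-length scalar) with multiple restarts. Branch lengths are
#' taken from the input tree and rescaled by a single free scalar per model.
#' The test statistic `lambda = 2 (lnL1 - lnL0)` is referred to chi-square
#' with 1 degree of freedom; `deltaOmega = omegaFg - omegaBg`, negative
#' meaning stronger purifying selection on the foreground.
#'
#' @param alignment a [CodonAlignment-class].
#' @param tree a [TaggedTree-class]; `foreground` overrides its tags when
#'   given.
#' @param foreground optional character vector of foreground tips.
#' @param freqMethod codon-frequency option, see [codonFrequencies()].
#' @param nStarts number of optimizer restarts for the alternative model
#'   (default 3; the null uses two fixed starts).
#' @param stem passed to [foregroundEdges()].
#' @param seed optional seed controlling restart jitter.
#' @param optControl control list passed to [stats::optim()] (bounded
#'   L-BFGS).
#' @return a one-row `data.frame`: `lnL0`, `lnL1`, `lambda`, `p`,
#'   `omegaBg`, `omegaFg`, `deltaOmega`, `kappa`, `converged`.
#' @export
branchModelLrt <- function(alignment, tree, foreground = NULL,
                           freqMethod = "F1x4", nStarts = 3,
                           stem = "include", seed = NULL,
                           optControl = list(maxit = 150, factr = 1e8)) {
    stopifnot(is(alignment, "CodonAlignment"), is(tree, "TaggedTree"))
    if (!is.null(foreground))
        tree <- taggedTree(tree@tree, foreground = foreground,
                           subclass = tree@subclass)
    if (!is.null(seed)) set.seed(seed)
    freqs <- codonFrequencies(alignment, method = freqMethod)
    ctx <- .likContext(alignment, tree, freqs, stem = stem)
    lower <- log(c(0.1, 1e-4, 1e-3))
    upper <- log(c(20, 10, 1e3))
    nll0 <- function(p) {
        v <- exp(p)
        -.ctxLoglik(ctx, kappa = v[1], omegaBg = v[2], scale = v[3])
    }
    fit1run <- function(fn, start, lo, hi) {
        tryCatch(optim(start, fn, method = "L-BFGS-B", lower = lo,
                       upper = hi, control = optControl),
                 error = function(e) list(value = Inf, par = start,
                                          convergence = 99L))
    }
    # the null surface is smooth in 3 parameters; two fixed starts suffice
    starts0 <- list(log(c(2, 0.3, 1)), log(c(4, 0.05, 1)))
    fits0 <- lapply(starts0, fit1run, fn = nll0, lo = lower, hi = upper)
    f0 <- fits0[[which.min(vapply(fits0, `[[`, numeric(1), "value"))]]
    nFg <- length(foregroundEdges(tree, stem = stem))
    if (nFg == 0L) {    # no foreground branches: models coincide
        v <- exp(f0$par)
        return(data.frame(lnL0 = -f0$value, lnL1 = -f0$value, lambda = 0,
                          p = 1, omegaBg = v[2], omegaFg = v[2],
                          deltaOmega = 0, kappa = v[1],
                          converged = f0$convergence == 0L))
    }
    lower1 <- log(c(0.1, 1e-4, 1e-4, 1e-3))
    upper1 <- log(c(20, 10, 10, 1e3))
    nll1 <- function(p) {
        v <- exp(p)
        -.ctxLoglik(ctx, kappa = v[1], omegaBg = v[2], omegaFg = v[3],
                    scale = v[4])
    }
    p0 <- f0$par
    starts1 <- list(c(p0[1], p0[2], p0[2], p0[3]),          # null optimum
                    c(p0[1], p0[2], p0[2] + log(0.3), p0[3]),
                    c(p0[1], p0[2], p0[2] - log(0.3), p0[3]))
    if (nStarts > 3)
        starts1 <- c(starts1, replicate(nStarts - 3, simplify = FALSE,
            p0[c(1, 2, 2, 3)] + c(0, 0, rnorm(1, 0, 1), 0)))
    fits1 <- lapply(starts1[seq_len(max(nStarts, 1))], fit1run,
                    fn = nll1, lo = lower1, hi = upper1)
    f1 <- fits1[[which.min(vapply(fits1, `[[`, numeric(1), "value"))]]
    lnL0 <- -f0$value; lnL1 <- -f1$value
    lambda <- max(2 * (lnL1 - lnL0), 0)
    v1 <- exp(f1$par)
    data.frame(lnL0 = lnL0, lnL1 = lnL1, lambda = lambda,
               p = pchisq(lambda, df = 1, lower.tail = FALSE),
               omegaBg = v1[2], omegaFg = v1[3],
               deltaOmega = v1[3] - v1[2], kappa = v1[1],
               converged = f0$convergence == 0L && f1$convergence == 0L &&
                   is.finite(lnL0) && is.finite(lnL1))
}
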