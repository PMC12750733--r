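# Independent oracles used across the suite. Each re-derives the quantity
# under test from first principles (enumeration, brute force, or the
# algorithm's textbook definition written out naively) without touching
# the package's implementation path.

# ---- TMM: straight-line reimplementation of the doubly trimmed,
# precision-weighted mean of log ratios --------------------------------
naiveTmmFactors <- function(cnt, trimM = 0.3, trimA = 0.05) {
    lib <- colSums(cnt)
    uq <- vapply(seq_len(ncol(cnt)), function(j)
        unname(quantile(cnt[, j], 0.75)) / lib[j], numeric(1))
    ref <- which.min(abs(uq - mean(uq)))
    f <- vapply(seq_len(ncol(cnt)), function(j) {
        obs <- cnt[, j] / lib[j]
        rf <- cnt[, ref] / lib[ref]
        keep <- obs > 0 & rf > 0
        logR <- log2(obs[keep] / rf[keep])
        absE <- (log2(obs[keep]) + log2(rf[keep])) / 2
        v <- (lib[j] - cnt[keep, j]) / (lib[j] * cnt[keep, j]) +
             (lib[ref] - cnt[keep, ref]) / (lib[ref] * cnt[keep, ref])
        if (max(abs(logR)) < 1e-6) return(1)
        n <- length(logR)
        loL <- floor(n * trimM) + 1; hiL <- n + 1 - loL
        loS <- floor(n * trimA) + 1; hiS <- n + 1 - loS
        sel <- rank(logR) >= loL & rank(logR) <= hiL &
               rank(absE) >= loS & rank(absE) <= hiS
        2^(sum(logR[sel] / v[sel]) / sum(1 / v[sel]))
    }, numeric(1))
    f / exp(mean(log(f)))
}

# ---- PIC as a linear map; whitening check uses the phylogenetic
# covariance matrix ----------------------------------------------------
picLinearMap <- function(tree, tips) {
    U <- vapply(seq_along(tips), function(i) {
        x <- setNames(numeric(length(tips)), tips)
        x[i] <- 1
        unname(picContrasts(tree, x))
    }, numeric(length(tips) - 1L))
    U   # (ncontrasts x ntips)
}

# ---- GY94 generator and likelihood from first principles -------------
oracleCodonTables <- function() {
    gc <- Biostrings::GENETIC_CODE
    codons <- sort(names(gc)[gc != "*"])
    list(codons = codons, aa = unname(gc[codons]))
}

oracleQ <- function(kappa, omega, freqs, tab = oracleCodonTables()) {
    n <- length(tab$codons)
    Q <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        ci <- strsplit(tab$codons[i], "")[[1]]
        cj <- strsplit(tab$codons[j], "")[[1]]
        dif <- which(ci != cj)
        if (length(dif) != 1) next
        rate <- freqs[j]
        pair <- sort(c(ci[dif], cj[dif]))
        if (identical(pair, c("A", "G")) || identical(pair, c("C", "T")))
            rate <- rate * kappa
        if (tab$aa[i] != tab$aa[j]) rate <- rate * omega
        Q[i, j] <- rate
    }
    diag(Q) <- -rowSums(Q)
    Q
}

# exhaustive ancestral-state summation for a 3-taxon rooted tree
# ((A:ta,B:tb):tab,C:tc); with per-branch omega class
bruteLoglik3 <- function(alnIdx, ta, tb, tab3, tc, kappa, omegaBg, freqs,
                         omegaA = omegaBg) {
    tabs <- oracleCodonTables()
    Qbg <- oracleQ(kappa, omegaBg, freqs, tabs)
    mu <- -sum(freqs * diag(Qbg))
    Qbg <- Qbg / mu
    Pa <- as.matrix(Matrix::expm(oracleQ(kappa, omegaA, freqs, tabs) /
                                 mu * ta))
    Pb <- as.matrix(Matrix::expm(Qbg * tb))
    Pn <- as.matrix(Matrix::expm(Qbg * tab3))
    Pc <- as.matrix(Matrix::expm(Qbg * tc))
    ll <- 0
    for (s in seq_len(ncol(alnIdx))) {
        a <- alnIdx["A", s]; b <- alnIdx["B", s]; cc <- alnIdx["C", s]
        lik <- 0
        for (r in 1:61) for (nn in 1:61)
            lik <- lik + freqs[r] * Pc[r, cc] * Pn[r, nn] *
                Pa[nn, a] * Pb[nn, b]
        ll <- ll + log(lik)
    }
    ll
}

# ---- stress centrality by exhaustive geodesic enumeration ------------
bruteStress <- function(g) {
    n <- igraph::vcount(g)
    S <- numeric(n)
    if (n < 3) return(S)
    for (s in seq_len(n - 1)) {
        asp <- suppressWarnings(
            igraph::all_shortest_paths(g, from = s, to = (s + 1):n))$res
        for (p in asp) {
            v <- as.integer(p)
            if (length(v) > 2) {
                mid <- v[2:(length(v) - 1)]
                S[mid] <- S[mid] + 1
            }
        }
    }
    S
}

# ---- connected components by flood fill ------------------------------
floodComponents <- function(edges, nodes) {
    comp <- setNames(seq_along(nodes), nodes)
    repeat {
        changed <- FALSE
        for (i in seq_len(nrow(edges))) {
            a <- edges[i, 1]; b <- edges[i, 2]
            m <- min(comp[a], comp[b])
            if (comp[a] != m || comp[b] != m) {
                comp[a] <- m; comp[b] <- m; changed <- TRUE
            }
        }
        if (!changed) break
    }
    unname(split(nodes, comp[nodes]))
}

# ---- all permutations of 1..n (for exact Spearman enumeration) -------
allPerms <- function(n) {
    if (n == 1) return(matrix(1L, 1, 1))
    sub <- allPerms(n - 1L)
    out <- matrix(0L, n * nrow(sub), n)
    r <- 0L
    for (k in seq_len(n)) {
        block <- cbind(k, sub + (sub >= k))
        out[r + seq_len(nrow(sub)), ] <- block
        r <- r + nrow(sub)
    }
    out
}

# small random tree with positive branch lengths
randomTree <- function(n, seed) {
    set.seed(seed)
    tr <- ape::rtree(n)
    tr$edge.length <- tr$edge.length + 0.05
    tr
}
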