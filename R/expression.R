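## Sex-bias classification, CPM filtering, TMM normalization, the
## empirical-null M/D differential-deposition statistic, and the
## TMM - sex-ratio Spearman correlation. The analysis order is fixed:
## filter -> TMM -> differential test -> correlation.

#' Classify an egg pool's sex bias from operator counts
#'
#' Several operators each report the fraction of early embryos showing the
#' aggregated paternal-mitochondria pattern (male-developing). The median
#' of the operator ratios is the sample's sex-bias proxy: at or above the
#' threshold the pool is `male_biased`; when the dispersed fraction
#' (1 - median) reaches the threshold it is `female_biased`; otherwise
#' `unassigned`.
#'
#' @param operatorRatios numeric vector of aggregated-pattern fractions in
#'   `[0, 1]`, one per operator.
#' @param threshold bias threshold (default 0.70).
#' @return one of `"male_biased"`, `"female_biased"`, `"unassigned"`.
#' @examples
#' classifySexBias(c(0.75, 0.72, 0.71))   # male_biased
#' classifySexBias(c(0.20, 0.25, 0.28))   # female_biased
#' @export
classifySexBias <- function(operatorRatios, threshold = 0.70) {
    if (!length(operatorRatios)) stop("no operator ratios supplied")
    if (any(operatorRatios < 0 | operatorRatios > 1))
        stop("operator ratios must lie in [0, 1]")
    m <- median(operatorRatios)
    if (m >= threshold) "male_biased"
    else if ((1 - m) >= threshold) "female_biased"
    else "unassigned"
}

#' Counts-per-million low-signal filter
#'
#' A feature is retained iff its CPM (`count / librarySize * 1e6`, library
#' sizes computed on the unfiltered matrix) reaches `minCpm` in at least
#' one sample; features below `minCpm` in all samples are excluded.
#'
#' @param counts an [EggCounts-class] or integer matrix.
#' @param minCpm retention threshold (default 2).
#' @return character vector of retained feature ids (rownames).
#' @export
cpmFilter <- function(counts, minCpm = 2) {
    cnt <- if (is(counts, "EggCounts")) counts(counts) else counts
    L <- colSums(cnt)
    if (any(L <= 0)) stop("library size 0 for some sample")
    cpm <- t(t(cnt) / L) * 1e6
    rownames(cnt)[rowSums(cpm >= minCpm) > 0]
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' Between-sample scaling factors by the weighted trimmed mean of log
#' expression ratios against a reference sample (the sample whose upper
#' quartile of CPM is closest to the mean upper quartile), doubly trimmed
#' on M (log ratio) and A (absolute expression), precision-weighted, and
#' rescaled to geometric mean 1 (via [edgeR::calcNormFactors()]). The
#' normalized value is the CPM computed on the effective library size
#' `L_s * f_s`.
#'
#' @param counts an [EggCounts-class] or integer matrix (already filtered).
#' @param trimM M-trim fraction (default 0.30).
#' @param trimA A-trim fraction (default 0.05).
#' @return list with `factors` (per-sample `f_s`), `libSizes`, and `norm`
#'   (the normalized matrix).
#' @export
tmmFactors <- function(counts, trimM = 0.30, trimA = 0.05) {
    cnt <- if (is(counts, "EggCounts")) counts(counts) else counts
    if (ncol(cnt) < 2) stop("TMM needs at least 2 samples")
    L <- colSums(cnt)
    f <- edgeR::calcNormFactors(cnt, method = "TMM", lib.size = L,
                                logratioTrim = trimM, sumTrim = trimA,
                                doWeighting = TRUE)
    norm <- t(t(cnt) / (L * f)) * 1e6
    list(factors = setNames(f, colnames(cnt)), libSizes = L, norm = norm)
}

# Fenwick (binary indexed) tree prefix counts, used for the joint
# (|M|, D) exceedance below
.fenwickAdd <- function(tree, i) {
    n <- length(tree)
    while (i <= n) { tree[i] <- tree[i] + 1; i <- i + bitwAnd(i, -i) }
    tree
}
.fenwickQuery <- function(tree, i) {
    s <- 0
    while (i > 0) { s <- s + tree[i]; i <- i - bitwAnd(i, -i) }
    s
}

# for each feature, the fraction of null (|M*|, D*) pairs jointly dominated
# by (|M|, D): offline sweep over |M| with a Fenwick tree over D* ranks
.jointNullProb <- function(absM, D, nullAbsM, nullD) {
    K <- length(nullAbsM)
    ordN <- order(nullAbsM)
    nullAbsM <- nullAbsM[ordN]; nullD <- nullD[ordN]
    dSorted <- sort(nullD)
    dRank <- findInterval(nullD, dSorted)     # rank of each null D*
    ordF <- order(absM)
    tree <- numeric(K)
    res <- numeric(length(absM))
    j <- 0L
    for (i in ordF) {
        while (j < K && nullAbsM[j + 1L] <= absM[i]) {
            j <- j + 1L
            tree <- .fenwickAdd(tree, dRank[j])
        }
        qi <- findInterval(D[i], dSorted)
        res[i] <- if (qi > 0) .fenwickQuery(tree, qi) else 0
    }
    res / K
}

#' Empirical-null differential-deposition test
#'
#' For every feature, `M = log2((xbarA + c) / (xbarB + c))` and
#' `D = |xbarA - xbarB|` are computed on the normalized values with
#' pseudo-count `c`. A null cloud of `(M*, D*)` pairs is built by drawing
#' features at random, permuting their values within each bias group, and
#' contrasting balanced sample splits that put half of each group on
#' either side, so that any genuine group signal cancels and only noise
#' remains. Because the raw difference `D` scales with expression level,
#' features are stratified into `nBins` abundance bins (quantiles of the
#' mean normalized value) and each feature is compared against the null
#' cloud of its own bin. The deposition probability is the fraction of
#' null pairs jointly dominated, `prob = P(|M*| <= |M| and D* <= D)`, and
#' a feature is called differentially deposited iff `prob > q`.
#'
#' @param norm normalized matrix (features x samples), e.g.
#'   `tmmFactors(...)$norm`.
#' @param groups two-level per-sample labels.
#' @param nNull total number of null pairs, spread over the bins
#'   (default `1e5`).
#' @param q call threshold on the deposition probability (default 0.95).
#' @param pseudoCount stabilizing constant `c` (default 0.5).
#' @param nBins abundance strata (default 10; 1 disables stratification).
#' @param seed integer seed.
#' @return data.frame: `feature_id`, `M`, `D`, `prob`, `called`,
#'   `direction` (level A up/down).
#' @export
deTest <- function(norm, groups, nNull = 1e5, q = 0.95, pseudoCount = 0.5,
                   nBins = 10, seed = 1) {
    lv <- unique(groups)
    if (length(lv) != 2) stop("groups must have exactly 2 levels")
    ia <- which(groups == lv[1]); ib <- which(groups == lv[2])
    if (length(ia) < 2 || length(ib) < 2)
        stop("need >= 2 samples per group")
    nBins <- max(1L, min(nBins, nrow(norm) %/% 20L))
    if (nNull / nBins < 1 / (1 - q))
        stop(sprintf("nNull = %d cannot resolve q = %g over %d bins; need >= %d",
                     nNull, q, nBins, nBins * ceiling(1 / (1 - q))))
    xa <- rowMeans(norm[, ia, drop = FALSE])
    xb <- rowMeans(norm[, ib, drop = FALSE])
    M <- log2((xa + pseudoCount) / (xb + pseudoCount))
    D <- abs(xa - xb)
    set.seed(seed)
    nf <- nrow(norm)
    ha <- length(ia) %/% 2; hb <- length(ib) %/% 2
    g1 <- c(ia[seq_len(ha)], ib[seq_len(hb)])
    g2 <- c(ia[-seq_len(ha)], ib[-seq_len(hb)])
    bins <- if (nBins > 1)
        cut(rank(rowMeans(norm), ties.method = "first"), nBins,
            labels = FALSE)
    else rep(1L, nf)
    nPerBin <- ceiling(nNull / nBins)
    prob <- numeric(nf)
    for (bn in seq_len(nBins)) {
        idx <- which(bins == bn)
        feat <- idx[sample.int(length(idx), nPerBin, replace = TRUE)]
        nullM <- nullD <- numeric(nPerBin)
        for (b in seq_len(nPerBin)) {
            v <- norm[feat[b], ]
            v[ia] <- v[ia][sample.int(length(ia))]
            v[ib] <- v[ib][sample.int(length(ib))]
            m1 <- mean(v[g1]); m2 <- mean(v[g2])
            nullM[b] <- log2((m1 + pseudoCount) / (m2 + pseudoCount))
            nullD[b] <- abs(m1 - m2)
        }
        prob[idx] <- .jointNullProb(abs(M[idx]), D[idx],
                                    abs(nullM), nullD)
    }
    data.frame(feature_id = rownames(norm), M = M, D = D, prob = prob,
               called = prob > q,
               direction = ifelse(M >= 0, paste0("up_", lv[1]),
                                  paste0("up_", lv[2])),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Spearman correlation of normalized expression with the sex ratio
#'
#' Exact p-value for n <= 9 (no ties), asymptotic otherwise, via
#' [stats::cor.test()].
#'
#' @param normRow normalized expression of one feature across samples.
#' @param sigma per-sample offspring sex ratios.
#' @return list with `rho` and `p`; a constant vector yields `rho = NA`
#'   with a warning flag.
#' @export
sexratioCorrelation <- function(normRow, sigma) {
    stopifnot(length(normRow) == length(sigma))
    if (length(normRow) < 4) stop("need at least 4 samples")
    if (sd(normRow) == 0 || sd(sigma) == 0) {
        warning("constant vector: Spearman correlation undefined")
        return(list(rho = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(
        cor.test(normRow, sigma, method = "spearman",
                 exact = length(normRow) <= 9))
    list(rho = unname(ct$estimate), p = ct$p.value)
}

# Spearman rho and p for every row of a matrix against one covariate.
# Tie-free rows share the exact small-sample null distribution of rho (a
# single enumeration over n! rankings); rows with ties fall back to
# stats::cor.test, which matches sexratioCorrelation() exactly.
.spearmanAll <- function(norm, sigma) {
    n <- length(sigma)
    nf <- nrow(norm)
    out <- list(rho = rep(NA_real_, nf), p = rep(NA_real_, nf))
    flat <- apply(norm, 1, sd) == 0
    if (sd(sigma) == 0) return(out)
    rx <- t(apply(norm, 1, rank))
    rs <- rank(sigma)
    hasTies <- apply(rx, 1, anyDuplicated) > 0 |
        anyDuplicated(rs) > 0
    rho <- as.vector((scale(t(rx)) |> crossprod(scale(rs))) / (n - 1))
    out$rho[!flat] <- rho[!flat]
    exactOk <- !hasTies & !flat & n <= 9
    if (any(exactOk)) {
        perms <- .allRankPerms(n)
        base <- scale(seq_len(n))[, 1]
        nullRho <- sort(as.vector(apply(perms, 1, function(pm)
            sum(base * base[pm])) / (n - 1)))
        K <- length(nullRho)
        r <- out$rho[exactOk]
        pl <- findInterval(r + 1e-12, nullRho) / K
        pu <- (K - findInterval(r - 1e-12, nullRho,
                                left.open = TRUE)) / K
        out$p[exactOk] <- pmin(1, 2 * pmin(pl, pu))
    }
    slow <- which(!flat & !exactOk)
    for (i in slow) {
        ct <- suppressWarnings(cor.test(norm[i, ], sigma,
                                        method = "spearman",
                                        exact = n <= 9))
        out$p[i] <- ct$p.value
    }
    out
}

.rankPermEnv <- new.env(parent = emptyenv())
.allRankPerms <- function(n) {
    key <- as.character(n)
    if (is.null(.rankPermEnv[[key]])) {
        perm1 <- function(k) {
            if (k == 1) return(matrix(1L, 1, 1))
            sub <- perm1(k - 1L)
            do.call(rbind, lapply(seq_len(k), function(j)
                cbind(j, sub + (sub >= j))))
        }
        .rankPermEnv[[key]] <- perm1(n)
    }
    .rankPermEnv[[key]]
}

#' Full differential-deposition stage
#'
#' Runs the fixed order: CPM filter, TMM normalization, empirical-null
#' test, and per-feature sex-ratio correlation.
#'
#' @param counts an [EggCounts-class].
#' @param minCpm,q,nNull,seed stage parameters (see the step functions).
#' @return list with `retained`, `factors`, `norm`, and `results` (the
#'   [deTest()] table extended with `rho` and `p_rho`).
#' @export
expressionStage <- function(counts, minCpm = 2, q = 0.95, nNull = 1e5,
                            seed = 1) {
    stopifnot(is(counts, "EggCounts"))
    keep <- cpmFilter(counts, minCpm = minCpm)
    cnt <- counts(counts)[keep, , drop = FALSE]
    tmm <- tmmFactors(cnt)
    res <- deTest(tmm$norm, biasLabel(counts), nNull = nNull, q = q,
                  seed = seed)
    cors <- .spearmanAll(tmm$norm, sexRatio(counts))
    res$rho <- cors$rho
    res$p_rho <- cors$p
    list(retained = keep, factors = tmm$factors, norm = tmm$norm,
         results = res)
}
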