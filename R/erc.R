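## Evolutionary rate covariation with the mitochondrial tree: root-to-tip
## distances, phylogenetic independent contrasts on the reference species
## tree, regression through the origin, and 2x2 enrichment tests.

#' Rate covariation of tip values through phylogenetic contrasts
#'
#' Core of [ercTest()], also usable directly on tip-value vectors (e.g. in
#' calibration simulations): both vectors are converted to phylogenetic
#' independent contrasts on the shared (pruned) reference tree and the gene
#' contrasts are regressed on the mitochondrial contrasts through the
#' origin, the standard regression for contrasts.
#'
#' @param geneValues,mitoValues named numeric tip-value vectors.
#' @param refTree reference [TaggedTree-class].
#' @param absolute regress absolute contrasts instead of signed ones
#'   (default `FALSE`).
#' @return list with `slope`, `correlation`, `p`, `nShared`, `nContrasts`.
#' @export
ercFromValues <- function(geneValues, mitoValues, refTree,
                          absolute = FALSE) {
    shared <- intersect(names(geneValues), names(mitoValues))
    shared <- intersect(shared, tipLabels(refTree))
    ug <- picContrasts(refTree, geneValues[shared])
    um <- picContrasts(refTree, mitoValues[shared])
    stopifnot(identical(names(ug), names(um)))
    if (absolute) { ug <- abs(ug); um <- abs(um) }
    n <- length(ug)
    sxx <- sum(um^2); sxy <- sum(um * ug); syy <- sum(ug^2)
    if (sxx <= 0 || syy <= 0)
        return(list(slope = NA_real_, correlation = NA_real_, p = NA_real_,
                    nShared = length(shared), nContrasts = n))
    beta <- sxy / sxx
    rss <- syy - beta * sxy
    df <- n - 1
    se <- sqrt(max(rss, 0) / df / sxx)
    tval <- if (se > 0) beta / se else sign(beta) * Inf
    p <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
    list(slope = beta, correlation = sxy / sqrt(sxx * syy), p = p,
         nShared = length(shared), nContrasts = n)
}

#' Evolutionary rate covariation of a gene tree with the mitochondrial tree
#'
#' Species root-to-tip distances of the gene tree are tested for
#' correlation against those of the mitochondrial tree; both distance
#' vectors are adjusted for phylogenetic structure by computing their
#' independent contrasts on the reference species tree (pruned to the
#' shared species) before fitting a linear regression through the origin.
#'
#' @param geneTree,mitoTree [TaggedTree-class] trees.
#' @param refTree the reference species tree the contrasts are computed on.
#' @param minShared minimum number of shared species (default 10).
#' @param absolute see [ercFromValues()].
#' @return one-row data.frame with `nShared`, `slope`, `correlation`, `p`,
#'   or `NULL` (with a message) when the species overlap is insufficient.
#' @export
ercTest <- function(geneTree, mitoTree, refTree, minShared = 10,
                    absolute = FALSE) {
    shared <- Reduce(intersect, list(tipLabels(geneTree),
                                     tipLabels(mitoTree),
                                     tipLabels(refTree)))
    if (length(shared) < minShared) {
        message("ERC skipped: only ", length(shared), " shared species (< ",
                minShared, ")")
        return(NULL)
    }
    dg <- rootToTip(pruneTo(geneTree, shared))
    dm <- rootToTip(pruneTo(mitoTree, shared))
    res <- ercFromValues(dg, dm, pruneTo(refTree, shared),
                         absolute = absolute)
    data.frame(nShared = res$nShared, slope = res$slope,
               correlation = res$correlation, p = res$p)
}

#' ERC scan over a gene set
#'
#' @param geneTrees named list of gene trees.
#' @param mitoTree,refTree see [ercTest()].
#' @param ... passed to [ercTest()].
#' @return data.frame with one row per tested gene.
#' @export
ercScan <- function(geneTrees, mitoTree, refTree, ...) {
    res <- lapply(geneTrees, ercTest, mitoTree = mitoTree,
                  refTree = refTree, ...)
    keep <- !vapply(res, is.null, logical(1))
    out <- do.call(rbind, res[keep])
    if (is.null(out)) return(NULL)
    cbind(gene_id = names(geneTrees)[keep], out, stringsAsFactors = FALSE)
}

#' 2x2 enrichment of a flag within a focal gene set
#'
#' Builds the `{focal, non-focal} x {flagged, non-flagged}` contingency
#' table over a gene universe and tests association by chi-square (no
#' continuity correction) or Fisher's exact test. Used both for the
#' over-representation of significant rate covariation among convergently
#' evolving genes and for the DE-CE overlap.
#'
#' @param focal,flagged,universe character gene-id vectors
#'   (`focal, flagged` must be subsets of `universe`).
#' @param method `"chi_square"` or `"fisher_exact"`.
#' @return list with `table` (2x2 matrix), `statistic` (chi-square only),
#'   `p`, `method`.
#' @export
enrichment2x2 <- function(focal, flagged, universe,
                          method = c("chi_square", "fisher_exact")) {
    method <- match.arg(method)
    stopifnot(all(focal %in% universe), all(flagged %in% universe))
    isFocal <- universe %in% focal
    isFlag <- universe %in% flagged
    tab <- matrix(c(sum(isFocal & isFlag), sum(isFocal & !isFlag),
                    sum(!isFocal & isFlag), sum(!isFocal & !isFlag)),
                  2, 2, byrow = TRUE,
                  dimnames = list(c("focal", "non_focal"),
                                  c("flagged", "non_flagged")))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        if (method == "chi_square")
            stop("degenerate margin: chi-square refused, use fisher_exact")
        return(list(table = tab, statistic = NA_real_, p = 1,
                    method = "fisher_exact"))
    }
    if (method == "chi_square") {
        ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
        list(table = tab, statistic = unname(ct$statistic),
             p = ct$p.value, method = method)
    } else {
        ft <- fisher.test(tab)
        list(table = tab, statistic = NA_real_, p = ft$p.value,
             method = method)
    }
}
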