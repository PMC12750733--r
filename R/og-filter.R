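## Orthogroup retention rules: alignment trimming, subclass-monophyly
## validation with 1-2-species rescue, and the species / foreground-count
## filter.

#' Trim an orthogroup alignment
#'
#' Columns whose missing fraction exceeds `maxColumnMissing` are removed
#' first; then sequences whose gap fraction in the trimmed alignment
#' exceeds `maxSeqGap` are removed. "Missing" in a column counts gap
#' characters and species absent from the orthogroup identically: when
#' `nSpeciesTotal` is larger than the number of sequences present, the
#' difference is added to every column's missing count. Set
#' `countAbsent = FALSE` to count only gap characters among the present
#' sequences.
#'
#' @param og an [OrthoGroup-class].
#' @param maxColumnMissing column removal threshold (default 0.5).
#' @param maxSeqGap sequence removal threshold (default 0.8).
#' @param nSpeciesTotal size of the species universe (default: the species
#'   present in the orthogroup).
#' @param countAbsent count absent species as missing (default `TRUE`).
#' @param gapChars characters treated as gaps (default `-`, `?`, `X`).
#' @return list with `og` (trimmed [OrthoGroup-class]), `removedColumns`,
#'   `removedSequences`, and `empty` (TRUE when no columns survive; such
#'   orthogroups are discarded downstream).
#' @export
trimAlignment <- function(og, maxColumnMissing = 0.5, maxSeqGap = 0.8,
                          nSpeciesTotal = NULL, countAbsent = TRUE,
                          gapChars = c("-", "?", "X")) {
    stopifnot(is(og, "OrthoGroup"))
    aln <- og@alignment
    if (!ncol(aln) || !nrow(aln)) stop("empty alignment")
    nPresent <- nrow(aln)
    nTotal <- if (countAbsent && !is.null(nSpeciesTotal))
        max(nSpeciesTotal, nPresent) else nPresent
    isGap <- matrix(aln %in% gapChars, nrow(aln), ncol(aln))
    colMissing <- (colSums(isGap) + (nTotal - nPresent)) / nTotal
    dropCol <- which(colMissing > maxColumnMissing)
    keepCol <- setdiff(seq_len(ncol(aln)), dropCol)
    if (!length(keepCol))
        return(list(og = new("OrthoGroup", ogId = og@ogId,
                             alignment = aln[, 0, drop = FALSE]),
                    removedColumns = dropCol,
                    removedSequences = character(0), empty = TRUE))
    aln2 <- aln[, keepCol, drop = FALSE]
    gapFrac <- rowMeans(matrix(aln2 %in% gapChars, nrow(aln2), ncol(aln2)))
    dropSeq <- rownames(aln2)[gapFrac > maxSeqGap]
    aln2 <- aln2[setdiff(rownames(aln2), dropSeq), , drop = FALSE]
    list(og = new("OrthoGroup", ogId = og@ogId, alignment = aln2),
         removedColumns = dropCol, removedSequences = dropSeq,
         empty = nrow(aln2) == 0L)
}

# is tip set 'tips' monophyletic on the unrooted topology? (i.e. some edge
# splits it from the rest)
.unrootedMonophyly <- function(tr, tips) {
    other <- setdiff(tr$tip.label, tips)
    if (length(tips) <= 1L || !length(other)) return(TRUE)
    # root at an outside tip, then test clade-hood
    rt <- ape::root(tr, outgroup = other[1L], resolve.root = TRUE)
    ape::is.monophyletic(rt, tips)
}

#' Validate subclass monophyly of a gene tree
#'
#' Each subclass must form a monophyletic group on the unrooted gene tree.
#' On failure, the smallest set of at most two species whose removal
#' restores monophyly of all subclasses is searched by brute force; an
#' empty `offending` set with `status = "fail"` means no such small fix
#' exists.
#'
#' @param geneTree a [TaggedTree-class] with subclass labels.
#' @return list with `status` (`"pass"`/`"fail"`), `offending` (character
#'   vector, possibly empty), and `vacuous` (TRUE when fewer than 3
#'   subclasses are represented, which passes with a warning).
#' @export
checkSubclassMonophyly <- function(geneTree) {
    stopifnot(is(geneTree, "TaggedTree"))
    sub <- subclassLabels(geneTree)
    if (!length(sub)) stop("gene tree has no subclass labels")
    tr <- ape::unroot(asPhylo(geneTree))
    sub <- sub[tr$tip.label]
    present <- unique(sub)
    if (length(present) < 3) {
        warning("fewer than 3 subclasses represented: vacuous pass")
        return(list(status = "pass", offending = character(0),
                    vacuous = TRUE))
    }
    allMono <- function(tree, labels) {
        labels <- labels[tree$tip.label]
        all(vapply(unique(labels), function(s)
            .unrootedMonophyly(tree, names(labels)[labels == s]),
            logical(1)))
    }
    if (allMono(tr, sub))
        return(list(status = "pass", offending = character(0),
                    vacuous = FALSE))
    tips <- sort(tr$tip.label)
    cand <- c(lapply(tips, identity),
              utils::combn(tips, 2, simplify = FALSE))
    for (rm in cand) {
        if (length(tr$tip.label) - length(rm) < 4) next
        tr2 <- ape::drop.tip(tr, rm)
        if (allMono(tr2, sub)) {
            return(list(status = "fail", offending = rm, vacuous = FALSE))
        }
    }
    list(status = "fail", offending = character(0), vacuous = FALSE)
}

#' Retention filter on orthogroup composition
#'
#' An orthogroup is retained iff it contains at least `minSpecies` species
#' and at least `minForeground` foreground (DUI) species. Applied after
#' trimming and monophyly rescue. The rule is idempotent and order-stable.
#'
#' @param ogs list of [OrthoGroup-class] objects, or a data.frame with
#'   columns `og_id`, `n_species`, `n_foreground`.
#' @param foreground character vector of foreground species ids (used when
#'   `ogs` is a list of orthogroups).
#' @param minSpecies minimum species count (default 15).
#' @param minForeground minimum foreground species count (default 4).
#' @return data.frame: `og_id`, `n_species`, `n_foreground`, `retained`.
#' @export
filterOrthogroups <- function(ogs, foreground = character(0),
                              minSpecies = 15, minForeground = 4) {
    if (is.data.frame(ogs)) {
        tab <- ogs
        stopifnot(all(c("og_id", "n_species", "n_foreground") %in%
                      colnames(tab)))
    } else {
        tab <- data.frame(
            og_id = vapply(ogs, function(o) o@ogId, character(1)),
            n_species = vapply(ogs, function(o) nrow(o@alignment),
                               integer(1)),
            n_foreground = vapply(ogs, function(o)
                sum(rownames(o@alignment) %in% foreground), integer(1)),
            stringsAsFactors = FALSE)
    }
    tab$retained <- tab$n_species >= minSpecies &
        tab$n_foreground >= minForeground
    tab
}

#' Full orthogroup-filter stage for a gene set with trees
#'
#' For each gene: trim the alignment (when one is supplied), validate
#' subclass monophyly on the gene tree with 1-2-species rescue (offending
#' species are removed from the tree and the orthogroup is marked
#' `rescued`), then apply the composition filter.
#'
#' @param geneTrees named list of [TaggedTree-class] gene trees with
#'   subclass labels.
#' @param foreground foreground species ids.
#' @param minSpecies,minForeground see [filterOrthogroups()].
#' @return list with `report` (data.frame: `og_id`, `n_species`,
#'   `n_foreground`, `status`, `rescued_species`, `retained`) and `trees`
#'   (the possibly rescued trees for retained genes).
#' @export
ogFilterStage <- function(geneTrees, foreground, minSpecies = 15,
                          minForeground = 4) {
    rows <- vector("list", length(geneTrees))
    outTrees <- list()
    for (i in seq_along(geneTrees)) {
        id <- names(geneTrees)[i]
        gt <- geneTrees[[i]]
        chk <- suppressWarnings(checkSubclassMonophyly(gt))
        status <- chk$status
        rescued <- character(0)
        if (status == "fail" && length(chk$offending) &&
            length(chk$offending) <= 2) {
            gt <- pruneTo(gt, setdiff(tipLabels(gt), chk$offending))
            rescued <- chk$offending
            status <- "rescued"
        }
        ns <- length(tipLabels(gt))
        nf <- sum(tipLabels(gt) %in% foreground)
        keep <- status != "fail" && ns >= minSpecies && nf >= minForeground
        rows[[i]] <- data.frame(
            og_id = id, n_species = ns, n_foreground = nf, status = status,
            rescued_species = paste(rescued, collapse = ","),
            retained = keep, stringsAsFactors = FALSE)
        if (keep) outTrees[[id]] <- gt
    }
    list(report = do.call(rbind, rows), trees = outTrees)
}
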