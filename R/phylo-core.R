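#' Parse a Newick string into a TaggedTree
#'
#' Thin wrapper around [ape::read.tree()] that validates the result:
#' duplicate tip labels and malformed strings raise errors naming the
#' offending token. Foreground tags and subclass labels are supplied
#' separately (see [taggedTree()]).
#'
#' @param text a single Newick string (terminating `;` required).
#' @param foreground,subclass passed to [taggedTree()].
#' @return a [TaggedTree-class].
#' @examples
#' tt <- parseNewick("((A:1,B:1):1,C:2);")
#' tipLabels(tt)
#' @export
parseNewick <- function(text, foreground = character(0),
                        subclass = character(0)) {
    stopifnot(is.character(text), length(text) == 1L)
    nopen <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
    nclose <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
    if (nopen != nclose)
        stop(sprintf("unbalanced parentheses: %d '(' vs %d ')'",
                     nopen, nclose))
    tr <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("Newick parse failure: ",
                                            conditionMessage(e)))
    if (is.null(tr)) stop("Newick parse failure: not a valid tree string")
    dup <- tr$tip.label[duplicated(tr$tip.label)]
    if (length(dup))
        stop(sprintf("duplicate tip label '%s'", dup[1L]))
    taggedTree(tr, foreground = foreground, subclass = subclass)
}

#' Serialize a TaggedTree to Newick
#'
#' @param tree a [TaggedTree-class] (or `"phylo"`).
#' @param digits significant digits for branch lengths (default 10).
#' @return a Newick string.
#' @export
writeNewick <- function(tree, digits = 10) {
    tr <- if (is(tree, "TaggedTree")) tree@tree else tree
    ape::write.tree(tr, digits = digits)
}

#' Root-to-tip path distances
#'
#' Sum of branch lengths on the path from the root to every tip, the raw
#' rate proxy used both by the relative-rate convergence scan and by the
#' mito-nuclear rate-covariation stage.
#'
#' @param tree a [TaggedTree-class] or rooted `"phylo"`.
#' @return named numeric vector, one distance per tip.
#' @examples
#' rootToTip(parseNewick("((A:1,B:1):1,C:2);"))
#' @export
rootToTip <- function(tree) {
    tr <- if (is(tree, "TaggedTree")) tree@tree else tree
    if (!ape::is.rooted(tr)) stop("rootToTip requires a rooted tree")
    if (is.null(tr$edge.length)) stop("tree has no branch lengths")
    ntip <- ape::Ntip(tr)
    nn <- ntip + tr$Nnode
    depth <- numeric(nn)
    # preorder: parents always precede children
    ord <- ape::reorder.phylo(tr, "postorder")
    edges <- ord$edge[rev(seq_len(nrow(ord$edge))), , drop = FALSE]
    len <- rev(ord$edge.length)
    for (i in seq_len(nrow(edges)))
        depth[edges[i, 2L]] <- depth[edges[i, 1L]] + len[i]
    setNames(depth[seq_len(ntip)], tr$tip.label)
}

#' Phylogenetic independent contrasts
#'
#' Standardized independent contrasts of a tip-value vector on a reference
#' tree (Felsenstein's pruning recursion, via [ape::pic()]). Tips without a
#' value are pruned first. Zero-length terminal branches receive an epsilon
#' of `1e-8` before contrast computation so that cherries with zero summed
#' branch length do not divide by zero; if an internal zero-length cherry
#' still yields a non-finite contrast an error points at this policy.
#' Contrasts are returned in a deterministic order (post-order over internal
#' nodes, keyed by the sorted labels of each node's descendant tips).
#'
#' @param refTree a [TaggedTree-class] or `"phylo"` reference tree.
#' @param values named numeric vector of tip values (names must be a subset
#'   of, and cover at least 3 of, the tree's tips... 2 tips give a single
#'   contrast).
#' @param epsilon added to zero-length terminal branches (default `1e-8`).
#' @return numeric vector of standardized contrasts, one per internal node
#'   used, named by a deterministic node key.
#' @examples
#' tt <- parseNewick("((A:1,B:1):1,C:2);")
#' picContrasts(tt, c(A = 1, B = 3, C = 2))
#' @export
picContrasts <- function(refTree, values, epsilon = 1e-8) {
    tr <- if (is(refTree, "TaggedTree")) refTree@tree else refTree
    if (is.null(names(values))) stop("'values' must be named by tip labels")
    if (!all(names(values) %in% tr$tip.label))
        stop("value names not among tree tips")
    keep <- intersect(tr$tip.label, names(values))
    if (length(keep) < 2L) stop("need at least 2 tips with values")
    if (length(keep) < length(tr$tip.label))
        tr <- ape::drop.tip(tr, setdiff(tr$tip.label, keep))
    if (!ape::is.binary(tr)) tr <- ape::multi2di(tr)
    term <- tr$edge[, 2L] <= ape::Ntip(tr)
    zero <- term & tr$edge.length <= 0
    if (any(zero)) tr$edge.length[zero] <- tr$edge.length[zero] + epsilon
    x <- values[tr$tip.label]
    pics <- tryCatch(ape::pic(x, tr),
                     error = function(e)
                         stop("contrast failure (zero-length cherry?): ",
                              conditionMessage(e),
                              "; see the epsilon policy in ?picContrasts"))
    if (any(!is.finite(pics)))
        stop("non-finite contrast; zero-length internal cherry - ",
             "adjust branch lengths or the epsilon policy (?picContrasts)")
    # deterministic ordering: key = sorted tip labels under each node
    ntip <- ape::Ntip(tr)
    keys <- vapply(as.integer(names(pics)), function(nd) {
        tips <- .descendantTips(tr, nd)
        paste(sort(tr$tip.label[tips]), collapse = "|")
    }, character(1))
    ord <- order(keys)
    setNames(unname(pics)[ord], keys[ord])
}

# tip indices descending from node nd (nd may be a tip)
.descendantTips <- function(tr, nd) {
    ntip <- ape::Ntip(tr)
    if (nd <= ntip) return(nd)
    out <- integer(0)
    stack <- nd
    while (length(stack)) {
        cur <- stack[[1L]]; stack <- stack[-1L]
        ch <- tr$edge[tr$edge[, 1L] == cur, 2L]
        out <- c(out, ch[ch <= ntip])
        stack <- c(stack, ch[ch > ntip])
    }
    out
}

#' Restrict a tagged tree to a tip subset
#'
#' @param tree a [TaggedTree-class].
#' @param tips character vector of tips to keep.
#' @return a [TaggedTree-class] on the retained tips, tags and subclass
#'   labels carried over.
#' @export
pruneTo <- function(tree, tips) {
    stopifnot(is(tree, "TaggedTree"))
    tr <- tree@tree
    drop <- setdiff(tr$tip.label, tips)
    if (length(drop) >= ape::Ntip(tr) - 1L)
        stop("cannot prune to fewer than 2 tips")
    if (length(drop)) tr <- ape::drop.tip(tr, drop)
    sub <- tree@subclass
    if (length(sub)) sub <- sub[tr$tip.label]
    taggedTree(tr, foreground = intersect(tree@foreground, tr$tip.label),
               subclass = sub)
}

#' Foreground branch set of a tagged tree
#'
#' Edge indices of the branches assigned to the foreground (DUI) class:
#' terminal branches of foreground tips plus internal branches all of whose
#' descendant tips are foreground ("DUI species clades"). Under this rule
#' the stem branch subtending each maximal foreground clade is itself
#' foreground (its subtree is entirely foreground); set `stem = "exclude"`
#' to assign those stem branches to the background instead.
#'
#' @param tree a [TaggedTree-class].
#' @param stem `"include"` (default) or `"exclude"` the stem branch of each
#'   maximal foreground clade.
#' @return integer vector of row indices into `asPhylo(tree)$edge`.
#' @export
foregroundEdges <- function(tree, stem = c("include", "exclude")) {
    stem <- match.arg(stem)
    stopifnot(is(tree, "TaggedTree"))
    tr <- tree@tree
    ntip <- ape::Ntip(tr)
    fgTip <- match(tree@foreground, tr$tip.label)
    if (!length(fgTip)) return(integer(0))
    nn <- ntip + tr$Nnode
    allFg <- logical(nn)
    allFg[fgTip] <- TRUE
    post <- ape::reorder.phylo(tr, "postorder")$edge
    # a node is all-foreground iff every child is
    nChild <- tabulate(post[, 1L], nn)
    fgChild <- integer(nn)
    for (i in seq_len(nrow(post))) {
        p <- post[i, 1L]; ch <- post[i, 2L]
        if (allFg[ch]) fgChild[p] <- fgChild[p] + 1L
        if (nChild[p] > 0L && fgChild[p] == nChild[p]) allFg[p] <- TRUE
    }
    sel <- allFg[tr$edge[, 2L]]
    if (stem == "exclude") {
        isStem <- sel & !allFg[tr$edge[, 1L]] &
            tr$edge[, 2L] > ntip        # only internal stems demoted
        sel <- sel & !isStem
    }
    which(sel)
}
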