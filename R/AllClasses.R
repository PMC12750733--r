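#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats median quantile rnorm runif rbinom rnbinom rlnorm rgamma
#'   setNames optim pchisq cor.test fisher.test chisq.test wilcox.test ks.test
#'   lm coef sd var complete.cases
#' @importFrom utils head write.table read.table combn
NULL

setOldClass("phylo")
setOldClass("igraph")

#' Rooted tree with DUI foreground tags and subclass labels
#'
#' Wraps an [ape::read.tree()] `"phylo"` tree together with the two tip
#' annotations the analysis needs: which tips belong to species with doubly
#' uniparental inheritance (DUI, the "foreground" trait), and which of the
#' three bivalve subclasses each tip belongs to.
#'
#' @slot tree a rooted binary `"phylo"` object with branch lengths
#'   (substitutions/site).
#' @slot foreground character vector of foreground (DUI) tip labels; may be
#'   empty.
#' @slot subclass named character vector mapping every tip label to one
#'   subclass label (or a zero-length vector when subclasses are unknown).
#'
#' @seealso [taggedTree()], [rootToTip()], [foregroundTips()]
#' @export
setClass("TaggedTree",
    representation(tree = "phylo", foreground = "character",
                   subclass = "character"))

setValidity("TaggedTree", function(object) {
    tr <- object@tree
    tips <- tr$tip.label
    msg <- character(0)
    if (anyDuplicated(tips))
        msg <- c(msg, sprintf("duplicate tip label '%s'",
                              tips[duplicated(tips)][1L]))
    if (is.null(tr$edge.length))
        msg <- c(msg, "tree has no branch lengths")
    else if (any(tr$edge.length < 0))
        msg <- c(msg, "negative branch lengths")
    if (!all(object@foreground %in% tips))
        msg <- c(msg, "foreground labels not among tip labels")
    if (length(object@subclass)) {
        if (!setequal(names(object@subclass), tips))
            msg <- c(msg, "subclass labels must be named by the tip labels")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a TaggedTree
#'
#' @param tree a `"phylo"` object (rooted, with branch lengths) or a Newick
#'   string.
#' @param foreground character vector of foreground (DUI) tip labels.
#' @param subclass named character vector of subclass labels, one per tip;
#'   optional.
#' @return a [TaggedTree-class] object.
#' @examples
#' tt <- taggedTree("((A:1,B:1):1,C:2);", foreground = "A")
#' rootToTip(tt)
#' @export
taggedTree <- function(tree, foreground = character(0),
                       subclass = character(0)) {
    if (is.character(tree)) tree <- parseNewick(tree)@tree
    if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object")
    new("TaggedTree", tree = tree, foreground = as.character(foreground),
        subclass = subclass)
}

#' In-frame codon alignment
#'
#' Stores an alignment as a taxa-by-site integer matrix over the 61 sense
#' codons of the standard genetic code; 0 marks a missing/gap codon.
#'
#' @slot codons integer matrix, rows named by taxa, entries in 0..61 indexing
#'   [senseCodons()] (0 = missing).
#' @export
setClass("CodonAlignment", representation(codons = "matrix"))

setValidity("CodonAlignment", function(object) {
    x <- object@codons
    if (is.null(rownames(x))) return("codon matrix must have taxon rownames")
    if (anyDuplicated(rownames(x))) return("duplicate taxon names")
    if (!is.numeric(x) || any(x != floor(x)) || any(x < 0) || any(x > 61))
        return("entries must be integers in 0..61")
    TRUE
})

#' Single-copy orthogroup alignment
#'
#' One aligned sequence per species, stored as a species-by-column character
#' matrix over an amino-acid (or nucleotide) alphabet plus the gap symbol
#' `"-"`.
#'
#' @slot ogId orthogroup identifier.
#' @slot alignment character matrix, rows named by species, single characters.
#' @export
setClass("OrthoGroup",
    representation(ogId = "character", alignment = "matrix"))

setValidity("OrthoGroup", function(object) {
    a <- object@alignment
    if (is.null(rownames(a))) return("alignment must have species rownames")
    if (anyDuplicated(rownames(a))) return("duplicate species in orthogroup")
    if (length(a) && any(nchar(a) != 1L))
        return("alignment cells must be single characters")
    TRUE
})

#' Orthogroup constructor
#'
#' @param ogId orthogroup identifier.
#' @param sequences named character vector of equal-length aligned sequences
#'   (gaps as `"-"`), or a character matrix of single residues.
#' @return an [OrthoGroup-class] object.
#' @export
orthoGroup <- function(ogId, sequences) {
    if (is.matrix(sequences)) {
        aln <- sequences
    } else {
        if (length(unique(nchar(sequences))) > 1L)
            stop("aligned sequences must have equal length")
        aln <- do.call(rbind, strsplit(sequences, ""))
        rownames(aln) <- names(sequences)
    }
    new("OrthoGroup", ogId = as.character(ogId), alignment = aln)
}

#' Egg-pool RNA-seq counts with sex-ratio metadata
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay
#' `"counts"` holds integer feature-by-sample counts and whose `colData`
#' carries the per-sample offspring sex ratio (`sexRatio`, fraction of
#' male-developing embryos in the progeny of the sampled female) and the
#' operator-derived bias label (`bias`, one of `male_biased`,
#' `female_biased`, `unassigned`).
#'
#' @export
setClass("EggCounts", contains = "SummarizedExperiment")

setValidity("EggCounts", function(object) {
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' missing")
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("sexRatio", "bias") %in% colnames(cd)))
        return("colData must contain 'sexRatio' and 'bias'")
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(cnt < 0)) return("negative counts")
    sr <- cd$sexRatio
    if (any(sr < 0 | sr > 1, na.rm = TRUE)) return("sexRatio outside [0,1]")
    TRUE
})

#' EggCounts constructor
#'
#' @param counts integer feature-by-sample count matrix.
#' @param sexRatio numeric vector in `[0,1]`, one value per sample (fraction
#'   of male-developing embryos).
#' @param bias per-sample bias label; defaults to `"unassigned"`.
#' @return an [EggCounts-class] object.
#' @export
eggCounts <- function(counts, sexRatio,
                      bias = rep("unassigned", ncol(counts))) {
    cd <- S4Vectors::DataFrame(sexRatio = as.numeric(sexRatio),
                               bias = as.character(bias),
                               row.names = colnames(counts))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd)
    new("EggCounts", se)
}

#' Scored protein-protein interaction network
#'
#' Undirected simple graph whose edges carry a confidence score in `[0,1]`
#' and whose nodes carry a set label (`DE_up_female`, `DE_up_male`, `CE`,
#' `other`). Edges below the minimum confidence score are dropped at
#' construction, mirroring the medium-confidence cutoff used when querying
#' interaction databases.
#'
#' @slot graph an [igraph::graph] object with vertex attribute `label` and
#'   edge attribute `score`.
#' @slot minScore minimum retained confidence score.
#' @export
setClass("Interactome",
    representation(graph = "igraph", minScore = "numeric"))

setValidity("Interactome", function(object) {
    g <- object@graph
    if (igraph::is_directed(g)) return("graph must be undirected")
    if (any(igraph::which_loop(g))) return("self-loops not allowed")
    if (any(igraph::which_multiple(g))) return("duplicate edges not allowed")
    sc <- igraph::E(g)$score
    if (is.null(sc)) return("edges must carry a 'score' attribute")
    if (length(sc) && any(sc < object@minScore - 1e-12))
        return("edges below minScore retained")
    TRUE
})

#' Interactome constructor
#'
#' @param edges data.frame with columns `node_a`, `node_b`, `score`.
#' @param labels optional named character vector of node set labels
#'   (`DE_up_female`, `DE_up_male`, `CE`, `other`); nodes absent from
#'   `labels` get `"other"`.
#' @param nodes optional character vector of node ids to include even when
#'   isolated; defaults to the union of edge endpoints and `names(labels)`.
#' @param minScore minimum confidence score; edges with `score < minScore`
#'   are dropped (default 0.400, the medium-confidence cutoff).
#' @return an [Interactome-class] object.
#' @export
interactome <- function(edges, labels = NULL, nodes = NULL,
                        minScore = 0.400) {
    stopifnot(all(c("node_a", "node_b", "score") %in% colnames(edges)))
    edges <- edges[edges$score >= minScore, , drop = FALSE]
    edges <- edges[as.character(edges$node_a) != as.character(edges$node_b), ,
                   drop = FALSE]
    if (is.null(nodes))
        nodes <- union(union(as.character(edges$node_a),
                             as.character(edges$node_b)), names(labels))
    nodes <- sort(unique(nodes))
    g <- igraph::graph_from_data_frame(
        data.frame(from = as.character(edges$node_a),
                   to = as.character(edges$node_b)),
        directed = FALSE, vertices = nodes)
    igraph::E(g)$score <- edges$score
    g <- igraph::simplify(g, edge.attr.comb = list(score = "max"))
    lab <- rep("other", length(nodes))
    names(lab) <- nodes
    if (!is.null(labels)) {
        keep <- intersect(names(labels), nodes)
        lab[keep] <- labels[keep]
    }
    igraph::V(g)$label <- unname(lab[igraph::V(g)$name])
    new("Interactome", graph = g, minScore = minScore)
}

setMethod("show", "TaggedTree", function(object) {
    cat(sprintf("TaggedTree: %d tips, %d foreground (DUI), %s\n",
        ape::Ntip(object@tree), length(object@foreground),
        if (length(object@subclass))
            sprintf("%d subclasses", length(unique(object@subclass)))
        else "no subclass labels"))
})

setMethod("show", "CodonAlignment", function(object) {
    cat(sprintf("CodonAlignment: %d taxa x %d codon sites\n",
        nrow(object@codons), ncol(object@codons)))
})

setMethod("show", "OrthoGroup", function(object) {
    cat(sprintf("OrthoGroup %s: %d species x %d columns\n",
        object@ogId, nrow(object@alignment), ncol(object@alignment)))
})

setMethod("show", "Interactome", function(object) {
    g <- object@graph
    cat(sprintf(
        "Interactome: %d nodes, %d edges (score >= %.3f); labels: %s\n",
        igraph::vcount(g), igraph::ecount(g), object@minScore,
        paste(names(table(igraph::V(g)$label)), collapse = ", ")))
})
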