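#' Tip labels of a tagged tree
#' @param x a [TaggedTree-class].
#' @return character vector of tip labels.
#' @export
setGeneric("tipLabels", function(x) standardGeneric("tipLabels"))

#' @rdname tipLabels
setMethod("tipLabels", "TaggedTree", function(x) x@tree$tip.label)

#' Foreground (DUI) tips of a tagged tree
#' @param x a [TaggedTree-class].
#' @return character vector of foreground tip labels.
#' @export
setGeneric("foregroundTips", function(x) standardGeneric("foregroundTips"))

#' @rdname foregroundTips
setMethod("foregroundTips", "TaggedTree", function(x) x@foreground)

#' Subclass labels of a tagged tree
#' @param x a [TaggedTree-class].
#' @return named character vector (tip -> subclass), possibly empty.
#' @export
setGeneric("subclassLabels", function(x) standardGeneric("subclassLabels"))

#' @rdname subclassLabels
setMethod("subclassLabels", "TaggedTree", function(x) x@subclass)

#' Underlying phylo object
#' @param x a [TaggedTree-class].
#' @return the `"phylo"` tree.
#' @export
setGeneric("asPhylo", function(x) standardGeneric("asPhylo"))

#' @rdname asPhylo
setMethod("asPhylo", "TaggedTree", function(x) x@tree)

#' @importFrom BiocGenerics counts
#' @export
setMethod("counts", "EggCounts", function(object)
    SummarizedExperiment::assay(object, "counts"))

#' Per-sample offspring sex ratio
#' @param x an [EggCounts-class].
#' @return numeric vector in `[0,1]`, one per sample.
#' @export
setGeneric("sexRatio", function(x) standardGeneric("sexRatio"))

#' @rdname sexRatio
setMethod("sexRatio", "EggCounts", function(x)
    SummarizedExperiment::colData(x)$sexRatio)

#' Per-sample sex-bias label
#' @param x an [EggCounts-class].
#' @return character vector of labels.
#' @export
setGeneric("biasLabel", function(x) standardGeneric("biasLabel"))

#' @rdname biasLabel
setMethod("biasLabel", "EggCounts", function(x)
    SummarizedExperiment::colData(x)$bias)

#' Underlying igraph object of an interactome
#' @param x an [Interactome-class].
#' @return an igraph graph.
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' @rdname asIgraph
setMethod("asIgraph", "Interactome", function(x) x@graph)

#' Node set labels of an interactome
#' @param x an [Interactome-class].
#' @return named character vector (node -> label).
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' @rdname nodeLabels
setMethod("nodeLabels", "Interactome", function(x)
    setNames(igraph::V(x@graph)$label, igraph::V(x@graph)$name))

#' Alignment matrix of an orthogroup
#' @param x an [OrthoGroup-class] or [CodonAlignment-class].
#' @return the underlying matrix.
#' @export
setGeneric("alignmentMatrix", function(x) standardGeneric("alignmentMatrix"))

#' @rdname alignmentMatrix
setMethod("alignmentMatrix", "OrthoGroup", function(x) x@alignment)

#' @rdname alignmentMatrix
setMethod("alignmentMatrix", "CodonAlignment", function(x) x@codons)
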