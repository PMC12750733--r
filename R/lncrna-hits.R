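## lncRNA genome-hit handling: retention filters, strand-aware gene
## containment with flanks, and resampling enrichment within a focal (DE)
## gene set. Coordinates are 0-based half-open internally; the tabular-hit
## and GFF-like readers convert on input.

#' Retention filter on similarity hits
#'
#' A hit is kept iff its alignment is longer than `minLen` bp, covers more
#' than `minCov` of the query lncRNA, and has identity higher than
#' `minIdent` percent. All three boundaries are strict.
#'
#' @param hits data.frame of hit records ([readHitTable()] /
#'   [hitRecords()] columns).
#' @param minLen alignment-length bound in bp (default 100).
#' @param minCov query-coverage bound (default 0.5).
#' @param minIdent identity bound in percent (default 90).
#' @return the retained subset of `hits`.
#' @export
filterHits <- function(hits, minLen = 100, minCov = 0.5, minIdent = 90) {
    hits[hits$alnLength > minLen & hits$coverage > minCov &
         hits$identity > minIdent, , drop = FALSE]
}

#' Assign hits to containing genes with orientation
#'
#' A hit is assigned to a gene iff its interval lies entirely within the
#' gene's interval extended by `flank` bp on both sides, on the same
#' sequence. Orientation is `antisense` when the hit's subject strand
#' opposes the gene's strand, `sense` otherwise. Hits contained in several
#' (overlapping) genes yield one assignment row per gene; hits on unknown
#' sequences are dropped with a warning.
#'
#' @param hits data.frame of hit records (0-based half-open `start`/`end`).
#' @param genes data.frame of gene intervals ([readGeneIntervals()] /
#'   [simulateGeneIntervals()] columns, 0-based half-open).
#' @param flank containment slack in bp (default 100).
#' @return data.frame: the assigned hits with `gene_id`, `gene_focal`,
#'   `orientation` columns (zero rows when nothing is contained).
#' @export
annotateContainment <- function(hits, genes, flank = 100) {
    unknown <- setdiff(unique(hits$subject), unique(genes$seqid))
    if (length(unknown)) {
        warning("hits on unknown sequences dropped: ",
                paste(unknown, collapse = ", "))
        hits <- hits[!hits$subject %in% unknown, , drop = FALSE]
    }
    if (!nrow(hits) || !nrow(genes)) {
        out <- hits[integer(0), , drop = FALSE]
        out$gene_id <- character(0); out$gene_focal <- logical(0)
        out$orientation <- character(0)
        return(out)
    }
    # to 1-based inclusive for IRanges
    hr <- GenomicRanges::GRanges(hits$subject,
        IRanges::IRanges(hits$start + 1L, hits$end), strand = hits$strand)
    gr <- GenomicRanges::GRanges(genes$seqid,
        IRanges::IRanges(pmax(genes$start - flank, 0L) + 1L,
                         genes$end + flank), strand = genes$strand)
    ov <- GenomicRanges::findOverlaps(hr, gr, type = "within",
                                      ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    out <- hits[qi, , drop = FALSE]
    out$gene_id <- genes$gene_id[si]
    out$gene_focal <- genes$focal[si]
    out$orientation <- ifelse(hits$strand[qi] == genes$strand[si],
                              "sense", "antisense")
    rownames(out) <- NULL
    out
}

#' Resampling enrichment of hits within a focal gene set
#'
#' Observed statistic: the number of assigned hits hosted by focal genes
#' (or, with `countMode = "genes"`, the number of distinct focal host
#' genes). The null draws random gene sets of size `|focal|` from the
#' universe and recounts; `p = (1 + #(null >= observed)) / (nResample + 1)`.
#' `perQuery = TRUE` additionally reports one test per query lncRNA.
#'
#' @param assignedHits data.frame from [annotateContainment()].
#' @param focalGenes,universeGenes character gene-id vectors
#'   (`focalGenes` a subset of `universeGenes`).
#' @param nResample number of resampled gene sets (default 999).
#' @param seed integer seed.
#' @param countMode `"hits"` (default) or `"genes"`.
#' @param perQuery also test each query separately (default `FALSE`).
#' @param lengthStrata optional named numeric vector of gene lengths; when
#'   given, null sets are drawn stratified by length tertile so longer
#'   genes (which capture more hits) are matched.
#' @param returnNull also return the resampled null counts (for
#'   calibration studies).
#' @return list with `observed`, `nullMean`, `p`, optionally `nullCounts`,
#'   and (when `perQuery`) `byQuery` (data.frame: `query`, `observed`,
#'   `nullMean`, `p`).
#' @export
hitEnrichment <- function(assignedHits, focalGenes, universeGenes,
                          nResample = 999, seed = 1,
                          countMode = c("hits", "genes"),
                          perQuery = FALSE, lengthStrata = NULL,
                          returnNull = FALSE) {
    countMode <- match.arg(countMode)
    if (!all(focalGenes %in% universeGenes))
        stop("focalGenes must be a subset of universeGenes")
    if (length(focalGenes) > length(universeGenes))
        stop("focal set larger than universe")
    universeGenes <- unique(universeGenes)
    focalGenes <- unique(focalGenes)
    set.seed(seed)
    nU <- length(universeGenes); k <- length(focalGenes)
    hitGene <- assignedHits$gene_id
    countIn <- function(set) {
        inSet <- hitGene %in% set
        if (countMode == "hits") sum(inSet)
        else length(unique(hitGene[inSet]))
    }
    drawSet <- if (is.null(lengthStrata)) {
        function() universeGenes[sample.int(nU, k)]
    } else {
        len <- lengthStrata[universeGenes]
        strat <- cut(rank(len, ties.method = "first"), 3, labels = FALSE)
        kPer <- tabulate(strat[universeGenes %in% focalGenes], 3)
        function() unlist(lapply(1:3, function(s) {
            pool <- universeGenes[strat == s]
            pool[sample.int(length(pool), min(kPer[s], length(pool)))]
        }))
    }
    obs <- countIn(focalGenes)
    nullCounts <- vapply(seq_len(nResample), function(b) countIn(drawSet()),
                         numeric(1))
    out <- list(observed = obs, nullMean = mean(nullCounts),
                p = (1 + sum(nullCounts >= obs)) / (nResample + 1))
    if (returnNull) out$nullCounts <- nullCounts
    if (perQuery) {
        qs <- sort(unique(assignedHits$query))
        out$byQuery <- do.call(rbind, lapply(qs, function(qq) {
            sub <- assignedHits[assignedHits$query == qq, , drop = FALSE]
            r <- hitEnrichment(sub, focalGenes, universeGenes,
                               nResample = nResample, seed = seed,
                               countMode = countMode,
                               lengthStrata = lengthStrata)
            data.frame(query = qq, observed = r$observed,
                       nullMean = r$nullMean, p = r$p,
                       stringsAsFactors = FALSE)
        }))
    }
    out
}
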