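## File-format frontends: FASTA via Biostrings, tab-separated tables with
## headered columns for counts, hits, intervals and edge lists.

#' Build a CodonAlignment from nucleotide sequences
#'
#' @param sequences named character vector of equal-length in-frame
#'   nucleotide sequences (length divisible by 3), or a
#'   [Biostrings::DNAStringSet]. Gap codons (`---`) and codons containing
#'   `N`/`-` are treated as missing.
#' @return a [CodonAlignment-class].
#' @export
codonAlignment <- function(sequences) {
    if (is(sequences, "DNAStringSet"))
        sequences <- setNames(as.character(sequences), names(sequences))
    if (is.null(names(sequences))) stop("sequences must be named")
    len <- unique(nchar(sequences))
    if (length(len) != 1L) stop("sequences must have equal length")
    if (len %% 3L != 0L)
        stop(sprintf("sequence length %d not divisible by 3", len))
    cd <- .codonData()
    nsite <- len %/% 3L
    idx <- matrix(0L, length(sequences), nsite,
                  dimnames = list(names(sequences), NULL))
    starts <- seq(1L, len, by = 3L)
    gc <- Biostrings::GENETIC_CODE
    stops <- names(gc)[gc == "*"]
    for (i in seq_along(sequences)) {
        cods <- toupper(substring(sequences[[i]], starts, starts + 2L))
        hit <- match(cods, cd$codons)
        bad <- which(is.na(hit) & !grepl("[-N]", cods))
        if (length(bad)) {
            if (cods[bad[1L]] %in% stops)
                stop(sprintf("in-frame stop codon %s in '%s' at codon %d",
                             cods[bad[1L]], names(sequences)[i], bad[1L]))
            stop(sprintf("unrecognized codon '%s' in '%s' at codon %d",
                         cods[bad[1L]], names(sequences)[i], bad[1L]))
        }
        hit[is.na(hit)] <- 0L
        idx[i, ] <- hit
    }
    new("CodonAlignment", codons = idx)
}

#' Read / write codon alignments as FASTA
#'
#' @param path FASTA file path.
#' @return `readCodonFasta`: a [CodonAlignment-class].
#' @export
readCodonFasta <- function(path) {
    seqs <- Biostrings::readDNAStringSet(path)
    codonAlignment(seqs)
}

#' @rdname readCodonFasta
#' @param alignment a [CodonAlignment-class].
#' @export
writeCodonFasta <- function(alignment, path) {
    cd <- .codonData()
    idx <- alignment@codons
    seqs <- apply(idx, 1, function(row)
        paste(ifelse(row > 0, cd$codons[pmax(row, 1L)], "---"),
              collapse = ""))
    Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(setNames(seqs, rownames(idx))), path)
    invisible(path)
}

#' Read / write orthogroup alignments as FASTA
#'
#' @param path FASTA file path.
#' @param ogId orthogroup id (default: file base name).
#' @return `readOrthoGroupFasta`: an [OrthoGroup-class].
#' @export
readOrthoGroupFasta <- function(path, ogId = NULL) {
    seqs <- Biostrings::readBStringSet(path)
    if (is.null(ogId)) ogId <- sub("\\.[^.]*$", "", basename(path))
    orthoGroup(ogId, setNames(as.character(seqs), names(seqs)))
}

#' @rdname readOrthoGroupFasta
#' @param og an [OrthoGroup-class].
#' @export
writeOrthoGroupFasta <- function(og, path) {
    seqs <- apply(og@alignment, 1, paste, collapse = "")
    Biostrings::writeXStringSet(
        Biostrings::BStringSet(setNames(seqs, rownames(og@alignment))), path)
    invisible(path)
}

#' Read a 12-column tabular similarity-hit file
#'
#' The common tabular hit dialect: `qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore`, no header, 1-based
#' inclusive coordinates, subject strand encoded by `sstart > send`.
#' Coordinates are normalized to 0-based half-open internally.
#'
#' @param path file path.
#' @param queryLengths named numeric vector giving the length of each query
#'   (needed for query coverage).
#' @return data.frame of hit records (see [hitRecords()]).
#' @export
readHitTable <- function(path, queryLengths) {
    cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore")
    x <- read.table(path, sep = "\t", header = FALSE, col.names = cols,
                    stringsAsFactors = FALSE)
    hitRecords(query = x$qseqid, subject = x$sseqid,
               sstart = pmin(x$sstart, x$send) - 1L,
               send = pmax(x$sstart, x$send),
               strand = ifelse(x$sstart <= x$send, "+", "-"),
               identity = x$pident, alnLength = x$length,
               qstart = x$qstart, qend = x$qend,
               queryLengths = queryLengths)
}

#' Assemble similarity-hit records
#'
#' @param query,subject ids.
#' @param sstart,send subject interval, 0-based half-open.
#' @param strand subject strand, `"+"` or `"-"`.
#' @param identity percent identity in `[0, 100]`.
#' @param alnLength alignment length in bp.
#' @param qstart,qend aligned query span (1-based inclusive).
#' @param queryLengths named vector of query lengths.
#' @return data.frame with a `coverage` column (aligned query span / query
#'   length).
#' @export
hitRecords <- function(query, subject, sstart, send, strand, identity,
                       alnLength, qstart, qend, queryLengths) {
    if (any(sstart >= send)) stop("hit intervals must satisfy start < end")
    if (any(identity < 0 | identity > 100))
        stop("identity must be in [0, 100]")
    qlen <- queryLengths[as.character(query)]
    if (any(is.na(qlen))) stop("missing query length for some hits")
    cov <- (abs(qend - qstart) + 1) / qlen
    if (any(cov < 0 | cov > 1 + 1e-9)) stop("coverage outside [0, 1]")
    data.frame(query = as.character(query), subject = as.character(subject),
               start = as.integer(sstart), end = as.integer(send),
               strand = as.character(strand), identity = identity,
               alnLength = as.integer(alnLength),
               coverage = pmin(cov, 1), stringsAsFactors = FALSE)
}

#' Read gene intervals from a GFF-like TSV
#'
#' Expected headered columns: `seqid`, `start`, `end`, `strand`, `gene_id`,
#' `focal` (logical; the DE flag). Coordinates in the file are 1-based
#' inclusive (GFF dialect) and normalized to 0-based half-open on read.
#'
#' @param path file path.
#' @return data.frame of gene intervals.
#' @export
readGeneIntervals <- function(path) {
    x <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
    need <- c("seqid", "start", "end", "strand", "gene_id")
    if (!all(need %in% colnames(x)))
        stop("missing columns: ",
             paste(setdiff(need, colnames(x)), collapse = ", "))
    x$start <- as.integer(x$start) - 1L   # to 0-based half-open
    x$end <- as.integer(x$end)
    if (is.null(x$focal)) x$focal <- FALSE
    if (any(x$start >= x$end)) stop("gene intervals must satisfy start < end")
    x
}

#' Read / write per-species tip values as 2-column TSV
#'
#' @param path file path (columns `species`, `value`).
#' @return `readTipValues`: named numeric vector.
#' @export
readTipValues <- function(path) {
    x <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
    stopifnot(all(c("species", "value") %in% colnames(x)))
    setNames(as.numeric(x$value), x$species)
}

#' @rdname readTipValues
#' @param values named numeric vector.
#' @export
writeTipValues <- function(values, path) {
    writeTsv(data.frame(species = names(values),
                        value = unname(values)), path)
}

#' Write a data.frame as headered TSV
#'
#' @param x data.frame.
#' @param path output path.
#' @export
writeTsv <- function(x, path) {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
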