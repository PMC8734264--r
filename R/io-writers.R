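# Writers for the downstream MSA tools. All emitted coordinates are 1-based,
# matching the conventions of the external formats; internal coordinates stay
# 0-based.

# Per-line profit at the best valid solution: the line weight plus the
# weight of the line's selected outgoing interaction edge (each endpoint of
# a matched edge owns one of the two directed twins). Used for T-Coffee
# library weights.
lineProfits <- function(aln, graph) {
    ln <- aln@lines
    if (nrow(ln) == 0L) return(numeric(0))
    prof <- lineWeights(graph)[ln + 1L]
    m <- aln@matching
    if (nrow(m) > 0L) {
        key <- paste(ln[, 1], ln[, 2])
        for (r in seq_len(nrow(m))) {
            a <- match(paste(m$li[r], m$lj[r]), key)
            b <- match(paste(m$mi[r], m$mj[r]), key)
            prof[a] <- prof[a] + m$weight[r]
            prof[b] <- prof[b] + m$weight[r]
        }
    }
    prof
}

tcoffeeWeights <- function(profits) {
    if (length(profits) == 0L) return(integer(0))
    top <- max(profits)
    if (top <= 0) return(rep(1L, length(profits)))
    pmin(100L, pmax(1L, as.integer(round(100 * profits / top))))
}

#' Write a T-Coffee library (TC_LIB_FORMAT_01)
#'
#' One `#a b` block per pairwise alignment, each listing the aligned residue
#' pairs with an integer weight in [1,100] reflecting sequence and structure
#' conservation: the line's profit (substitution score plus half of each
#' incident matched interaction weight) scaled by the maximum profit in that
#' alignment.
#'
#' @param results list of [StructuralAlignment-class] objects covering
#'   distinct sequence pairs.
#' @param seqs named character vector of the input sequences.
#' @param path output file.
#' @param graphs optional list of [AlignmentGraph-class] objects parallel to
#'   `results`, used for profit-based weights; without it all weights are
#'   emitted as 50.
#' @return Invisibly, `path`.
#' @export
writeTcoffeeLibrary <- function(results, seqs, path, graphs = NULL) {
    if (length(results) == 0L) stop("nothing to write: empty result list")
    ids <- names(seqs)
    out <- c("! TC_LIB_FORMAT_01", sprintf("%d", length(seqs)),
             sprintf("%s %d %s", ids, nchar(seqs), seqs))
    for (k in seq_along(results)) {
        aln <- results[[k]]
        a <- match(aln@id1, ids); b <- match(aln@id2, ids)
        if (is.na(a) || is.na(b))
            stop("alignment references unknown sequence id: ",
                 aln@id1, " / ", aln@id2)
        ln <- aln@lines
        w <- if (is.null(graphs)) rep(50L, nrow(ln))
             else tcoffeeWeights(lineProfits(aln, graphs[[k]]))
        out <- c(out, sprintf("#%d %d", a, b))
        if (nrow(ln) > 0L)
            out <- c(out, sprintf("%d %d %d", ln[, 1] + 1L, ln[, 2] + 1L, w))
    }
    out <- c(out, "! SEQ_1_TO_N")
    writeLines(out, path)
    invisible(path)
}

#' Re-parse a T-Coffee library
#'
#' Inverse of [writeTcoffeeLibrary()] as far as the pairings are concerned;
#' used for round-trip validation.
#'
#' @param path library file.
#' @return List with `seqs` (named character) and `pairs`, a list (one entry
#'   per `#a b` block) of data.frames `id1,id2,pos1,pos2,weight` with 1-based
#'   positions.
#' @export
readTcoffeeLibrary <- function(path) {
    lines <- readLines(path)
    if (!startsWith(lines[1], "! TC_LIB_FORMAT"))
        stop("not a TC_LIB file: ", path)
    ns <- as.integer(lines[2])
    seqrec <- strsplit(lines[2 + seq_len(ns)], "[ \t]+")
    seqs <- stats::setNames(vapply(seqrec, `[`, character(1), 3L),
                            vapply(seqrec, `[`, character(1), 1L))
    ids <- names(seqs)
    blocks <- list()
    curA <- curB <- NA_integer_
    for (ln in lines[-seq_len(2 + ns)]) {
        if (startsWith(ln, "!") || !nzchar(trimws(ln))) next
        if (startsWith(ln, "#")) {
            f <- as.integer(strsplit(sub("^#", "", ln), "[ \t]+")[[1]])
            curA <- f[1]; curB <- f[2]
            blocks[[length(blocks) + 1L]] <- data.frame(
                id1 = character(0), id2 = character(0),
                pos1 = integer(0), pos2 = integer(0), weight = integer(0))
        } else {
            f <- as.integer(strsplit(trimws(ln), "[ \t]+")[[1]])
            blocks[[length(blocks)]] <- rbind(
                blocks[[length(blocks)]],
                data.frame(id1 = unname(ids[curA]), id2 = unname(ids[curB]),
                           pos1 = f[1], pos2 = f[2], weight = f[3]))
        }
    }
    list(seqs = seqs, pairs = blocks)
}

#' Write MAFFT-style pairwise alignment blocks
#'
#' Three lines per pairwise alignment: a FASTA-like header carrying both
#' sequence identifiers, then the two gapped rows of equal length.
#'
#' @param results list of [StructuralAlignment-class] objects.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writeMafftPairs <- function(results, path) {
    if (length(results) == 0L) stop("nothing to write: empty result list")
    out <- unlist(lapply(results, function(aln) {
        stopifnot(nchar(aln@row1) == nchar(aln@row2))
        c(sprintf(">%s %s", aln@id1, aln@id2), aln@row1, aln@row2)
    }))
    writeLines(out, path)
    invisible(path)
}

#' Write a single pairwise alignment as aligned FASTA
#'
#' Exactly four lines: first identifier, first gapped row, second
#' identifier, second gapped row. Only meaningful for a two-sequence run,
#' where no multiple alignment is needed.
#'
#' @param results list containing exactly one [StructuralAlignment-class].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writeAlignedFasta <- function(results, path) {
    if (length(results) != 1L)
        stop("aligned FASTA output requires exactly one pairwise result; got ",
             length(results))
    aln <- results[[1]]
    writeLines(c(paste0(">", aln@id1), aln@row1,
                 paste0(">", aln@id2), aln@row2), path)
    invisible(path)
}

#' Read a (multiple) alignment from aligned FASTA
#'
#' @param path aligned FASTA file; all rows must have equal length.
#' @return Named character vector of gapped rows.
#' @export
readAlignedFasta <- function(path) {
    set <- Biostrings::readBStringSet(path)
    rows <- toupper(as.character(set))
    names(rows) <- vapply(strsplit(names(set), "[ \t]+"), `[`, character(1), 1L)
    if (length(unique(nchar(rows))) > 1L)
        stop("alignment rows differ in length in ", path)
    rows
}
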