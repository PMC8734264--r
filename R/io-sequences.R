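#' Read RNA sequences from a FASTA file
#'
#' Sequences are normalised to uppercase and DNA-style `T` is transliterated
#' to `U`; any residue outside `A,C,G,U,N` after normalisation is an error.
#' Identifiers are the first whitespace-delimited token of each header.
#'
#' @param path path to a multi-record FASTA file (or a connection readable by
#'   [Biostrings::readBStringSet()]).
#' @return Named character vector of RNA sequences over `{A,C,G,U,N}`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1 some description", "acgt", ">s2", "GGNCC"), fa)
#' readRnaFasta(fa)
#' @export
readRnaFasta <- function(path) {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L)
        stop("no sequences in ", path)
    ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, character(1), 1L)
    seqs <- toupper(as.character(set))
    names(seqs) <- ids
    vapply(seq_along(seqs), function(k) normalizeRna(seqs[[k]], ids[[k]]),
           character(1)) -> out
    names(out) <- ids
    out
}

# uppercase, T->U, validate alphabet; reports the 1-based offending position
normalizeRna <- function(residues, id = "sequence") {
    r <- chartr("Tt", "Uu", toupper(residues))
    bad <- regexpr("[^ACGUN]", r)
    if (bad > 0L)
        stop(sprintf("invalid residue '%s' at %d in %s",
                     substr(r, bad, bad), as.integer(bad), id))
    if (nchar(r) < 1L)
        stop("empty sequence: ", id)
    r
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeFasta <- function(seqs, path) {
    set <- Biostrings::BStringSet(seqs)
    Biostrings::writeXStringSet(set, path)
    invisible(path)
}
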