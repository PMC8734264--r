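# Substitution scoring for line weights.
#
# Default scheme is the RIBOSUM85-60 single-nucleotide matrix (log-odds
# scores derived from rRNA alignments at >= 85% identity against a 60%
# background set), the standard choice for structural RNA aligners. The
# wildcard N scores 0 against everything.

ribosum8560 <- local({
    m <- matrix(c(
         2.22, -1.86, -1.46, -1.39,
        -1.86,  1.16, -2.48, -1.05,
        -1.46, -2.48,  1.03, -1.74,
        -1.39, -1.05, -1.74,  1.20), 4, 4, byrow = TRUE,
        dimnames = list(c("A", "C", "G", "U"), c("A", "C", "G", "U")))
    m
})

padWithN <- function(m) {
    out <- matrix(0, 5, 5, dimnames = list(c(rownames(m), "N"),
                                           c(colnames(m), "N")))
    out[rownames(m), colnames(m)] <- m
    out
}

#' Substitution matrices for RNA line weights
#'
#' `substMatrix("ribosum85-60")` returns the RIBOSUM85-60 single-nucleotide
#' log-odds matrix; `substMatrix("simple")` scores +4 for a match and -2 for
#' a mismatch. Both are extended with an `N` row/column scoring 0 against
#' everything.
#'
#' @param name `"ribosum85-60"` (default) or `"simple"`.
#' @return 5 x 5 numeric matrix over `A,C,G,U,N`.
#' @export
substMatrix <- function(name = c("ribosum85-60", "simple")) {
    name <- match.arg(name)
    if (name == "simple") {
        m <- matrix(-2, 4, 4, dimnames = dimnames(ribosum8560))
        diag(m) <- 4
        return(padWithN(m))
    }
    padWithN(ribosum8560)
}

#' Load a substitution matrix from a plain-text file
#'
#' Expects a whitespace-separated square table with residue names as header
#' row and first column (the layout `write.table(m, quote=FALSE)` emits).
#' An `N` row/column scoring 0 is appended if absent.
#'
#' @param path matrix file.
#' @return 5 x 5 numeric matrix over `A,C,G,U,N`.
#' @export
loadSubstMatrix <- function(path) {
    m <- as.matrix(utils::read.table(path, header = TRUE, row.names = 1,
                                     check.names = FALSE))
    storage.mode(m) <- "double"
    if (!identical(rownames(m), colnames(m)))
        stop("substitution matrix must have matching row/column names")
    if (!all(c("A", "C", "G", "U") %in% rownames(m)))
        stop("substitution matrix must cover A, C, G, U")
    if (!"N" %in% rownames(m)) m <- padWithN(m[c("A","C","G","U"),
                                               c("A","C","G","U")])
    m[c("A", "C", "G", "U", "N"), c("A", "C", "G", "U", "N")]
}
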