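#' @useDynLib knotAlign, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Base-pair probability matrix
#'
#' An n x n symmetric matrix whose entry (i,j) is the equilibrium probability
#' that positions i and j of one RNA sequence form a base pair. Because a
#' nucleotide pairs with at most one partner in expectation, every row sum is
#' at most 1 (up to a small numerical slack).
#'
#' @slot prob numeric matrix, symmetric, entries in [0,1].
#' @exportClass BasePairProbMatrix
setClass("BasePairProbMatrix", representation(prob = "matrix"))

setValidity("BasePairProbMatrix", function(object) {
    p <- object@prob
    if (!is.numeric(p) || nrow(p) != ncol(p))
        return("'prob' must be a square numeric matrix")
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1 + 1e-9))
        return("probabilities must lie in [0, 1]")
    if (max(abs(p - t(p))) > 1e-9)
        return("matrix must be symmetric")
    if (nrow(p) > 0 && any(rowSums(p) > 1 + 1e-6))
        return("row sums exceed 1: a base pairs with at most one partner in expectation")
    TRUE
})

#' Construct a BasePairProbMatrix
#'
#' @param prob square symmetric numeric matrix of pairing probabilities.
#' @return A [BasePairProbMatrix-class] object.
#' @examples
#' m <- matrix(0, 6, 6); m[1, 6] <- m[6, 1] <- 0.9
#' bppm(m)
#' @export
bppm <- function(prob) {
    new("BasePairProbMatrix", prob = as.matrix(prob))
}

#' @describeIn bppm number of sequence positions covered by the matrix.
#' @param x a `BasePairProbMatrix`.
#' @export
bppmLength <- function(x) nrow(x@prob)

#' @describeIn bppm the raw probability matrix.
#' @export
probMatrix <- function(x) x@prob

setMethod("show", "BasePairProbMatrix", function(object) {
    n <- bppmLength(object)
    nz <- sum(object@prob[upper.tri(object@prob)] > 0)
    cat(sprintf("BasePairProbMatrix: %d positions, %d non-zero pairs\n", n, nz))
})

#' Alignment graph of two structured RNA sequences
#'
#' The graph underlying one pairwise sequence-structure alignment. A *line*
#' is a vertical edge aligning position i of sequence 1 with position j of
#' sequence 2; its weight is the substitution score of the two nucleotides.
#' An *interaction edge* connects the line of the left partners of one base
#' pair per sequence with the line of the right partners, and carries weight
#' (p1+p2)/2, the mean of the two pairing probabilities. Each undirected
#' interaction edge stands for the two directed edges (l,m) and (m,l) of the
#' ILP formulation; Lagrange multipliers are attached per direction.
#'
#' Lines are not materialised as n1*n2 objects: their weights are stored as a
#' dense score matrix, and only lines incident to interaction edges appear in
#' the edge table.
#'
#' @slot id1,id2 sequence identifiers.
#' @slot seq1,seq2 the two RNA sequences (character scalars).
#' @slot lineWeights n1 x n2 matrix of substitution scores w_l.
#' @slot edges data.frame with 0-based columns `li,lj` (left line), `mi,mj`
#'   (right line) and `weight` = (p1+p2)/2; one row per undirected edge.
#' @exportClass AlignmentGraph
setClass("AlignmentGraph", representation(
    id1 = "character", id2 = "character",
    seq1 = "character", seq2 = "character",
    lineWeights = "matrix", edges = "data.frame"))

setValidity("AlignmentGraph", function(object) {
    n1 <- nchar(object@seq1); n2 <- nchar(object@seq2)
    if (!identical(dim(object@lineWeights), c(n1, n2)))
        return("lineWeights must be n1 x n2")
    e <- object@edges
    need <- c("li", "lj", "mi", "mj", "weight")
    if (!all(need %in% names(e)))
        return("edges must have columns li, lj, mi, mj, weight")
    if (nrow(e) > 0) {
        if (any(e$li < 0 | e$mi >= n1 | e$lj < 0 | e$mj >= n2))
            return("edge endpoints out of sequence bounds")
        if (any(e$li >= e$mi) || any(e$lj >= e$mj))
            return("edges must join a left-partner line to a right-partner line")
        if (any(!is.finite(e$weight)))
            return("edge weights must be finite")
    }
    TRUE
})

#' @describeIn buildAlignmentGraph number of directed interaction edges
#'   (twice the undirected edge count, since every edge has a reverse twin).
#' @export
numInteractionEdges <- function(graph) 2L * nrow(graph@edges)

#' @describeIn buildAlignmentGraph the undirected interaction-edge table.
#' @export
interactionEdges <- function(graph) graph@edges

#' @describeIn buildAlignmentGraph the n1 x n2 matrix of line weights w_l.
#' @export
lineWeights <- function(graph) graph@lineWeights

setMethod("show", "AlignmentGraph", function(object) {
    cat(sprintf(
        "AlignmentGraph: %s (n=%d) x %s (n=%d), %d directed interaction edges\n",
        object@id1, nchar(object@seq1), object@id2, nchar(object@seq2),
        numInteractionEdges(object)))
})

#' Structural alignment of two RNA sequences
#'
#' The result of a pairwise sequence-structure alignment: the active lines
#' (equivalently the two gapped rows), the selected interaction matching, and
#' the score decomposition. When produced by [solvePairwise()] the object
#' additionally records the Lagrange bounds: `zUpper` (best relaxed score,
#' an upper bound on the optimum) and `zLower` (score of the best valid
#' solution found, which is the alignment stored here).
#'
#' @slot id1,id2 sequence identifiers.
#' @slot row1,row2 gapped alignment rows of equal length.
#' @slot lines integer matrix (k x 2) of 0-based aligned position pairs.
#' @slot matching data.frame of selected interaction edges
#'   (columns `li,lj,mi,mj,weight`); crossing rows are permitted (pseudoknots).
#' @slot sequenceScore sum of active line weights plus gap costs.
#' @slot structureScore total weight of the matching.
#' @slot zUpper,zLower best upper/lower Lagrange bounds.
#' @slot iterations number of Lagrange iterations performed.
#' @slot converged logical: did the bounds meet within tolerance?
#' @slot trace data.frame with per-iteration bound trajectories
#'   (columns `zU`, `zL`, `zUbest`, `zLbest`), possibly empty.
#' @exportClass StructuralAlignment
setClass("StructuralAlignment", representation(
    id1 = "character", id2 = "character",
    row1 = "character", row2 = "character",
    lines = "matrix", matching = "data.frame",
    sequenceScore = "numeric", structureScore = "numeric",
    zUpper = "numeric", zLower = "numeric",
    iterations = "integer", converged = "logical",
    trace = "data.frame"))

setValidity("StructuralAlignment", function(object) {
    if (nchar(object@row1) != nchar(object@row2))
        return("alignment rows must have equal length")
    if (ncol(object@lines) != 2)
        return("lines must be a k x 2 matrix")
    k <- nrow(object@lines)
    if (k > 1) {
        d1 <- diff(object@lines[, 1]); d2 <- diff(object@lines[, 2])
        if (any(d1 <= 0) || any(d2 <= 0))
            return("active lines must be strictly increasing in both sequences (non-crossing)")
    }
    TRUE
})

#' @describeIn solvePairwise total score (sequence + structure part).
#' @export
totalScore <- function(x) x@sequenceScore + x@structureScore

#' @describeIn solvePairwise matrix of 0-based aligned position pairs.
#' @export
activeLines <- function(x) x@lines

#' @describeIn solvePairwise data.frame of matched interaction edges.
#' @export
alignmentMatching <- function(x) x@matching

#' @describeIn solvePairwise the two gapped rows as a named character vector.
#' @export
alignedRows <- function(x) stats::setNames(c(x@row1, x@row2), c(x@id1, x@id2))

setMethod("show", "StructuralAlignment", function(object) {
    cat(sprintf("StructuralAlignment: %s / %s\n", object@id1, object@id2))
    cat(" ", object@row1, "\n ", object@row2, "\n", sep = "")
    cat(sprintf("  sequence %.4f + structure %.4f = %.4f\n",
                object@sequenceScore, object@structureScore, totalScore(object)))
    if (length(object@iterations) && !is.na(object@iterations))
        cat(sprintf("  bounds zL=%.4f zU=%.4f after %d iteration(s)%s\n",
                    object@zLower, object@zUpper, object@iterations,
                    if (isTRUE(object@converged)) " [converged]" else ""))
})
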