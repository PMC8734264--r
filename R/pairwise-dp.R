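# Global alignment under a position-specific score matrix: the solver of
# the relaxed problem. The DP itself is compiled (src/nw.cpp).

#' Gap model for global alignment
#'
#' A gap run of length d costs `open + (d-1)*extend` under the affine model;
#' the linear model charges `open` per gap character (equivalently, affine
#' with `extend == open`). Penalties must be non-positive.
#'
#' @param kind `"affine"` (default) or `"linear"`.
#' @param open gap-open score (cost of the first gap character), `<= 0`.
#' @param extend gap-extension score, `<= 0`; ignored for `"linear"`.
#' @return List of class `gapModel`.
#' @export
gapModel <- function(kind = c("affine", "linear"), open = -6, extend = -2) {
    kind <- match.arg(kind)
    stopifnot(open <= 0, extend <= 0)
    if (kind == "linear") extend <- open
    structure(list(kind = kind, open = open, extend = extend),
              class = "gapModel")
}

#' Global alignment with position-specific scores
#'
#' Needleman-Wunsch/Gotoh over an arbitrary profit matrix: maximises the sum
#' of `pssm[i, j]` over aligned position pairs plus gap costs. The returned
#' lines are strictly increasing in both coordinates, so the conflict-free
#' constraint of the alignment model holds by construction. Traceback ties
#' are broken diagonal > vertical > horizontal, making the result
#' deterministic.
#'
#' @param pssm numeric n1 x n2 matrix of position-specific profits.
#' @param gap a [gapModel()].
#' @return List with `score` (numeric) and `lines` (k x 2 integer matrix of
#'   0-based aligned pairs).
#' @examples
#' globalAlign(matrix(5, 1, 1))            # score 5, one line
#' globalAlign(matrix(0, 0, 2), gapModel("linear", open = -2))  # score -4
#' @export
globalAlign <- function(pssm, gap = gapModel()) {
    stopifnot(is.matrix(pssm))
    storage.mode(pssm) <- "double"
    res <- .nw_align_cpp(pssm, gap$open, gap$extend)
    list(score = res$score, lines = res$lines, ops = res$ops)
}

#' Batch of global alignments
#'
#' Elementwise identical to mapping [globalAlign()] over the list; results
#' do not depend on batch size or worker count (the lock-step batching is a
#' semantics-only contract; numerics are identical either way).
#'
#' @param pssms non-empty list of profit matrices.
#' @param gap a [gapModel()].
#' @param workers number of worker processes (forked; results identical for
#'   any value).
#' @return List of [globalAlign()] results in input order.
#' @export
batchAlign <- function(pssms, gap = gapModel(), workers = 1L) {
    stopifnot(length(pssms) >= 1L)
    if (workers > 1L && .Platform$OS.type == "unix") {
        parallel::mclapply(pssms, globalAlign, gap = gap, mc.cores = workers)
    } else {
        lapply(pssms, globalAlign, gap = gap)
    }
}

# Affine-optimal gap cost of a fixed line set: unmatched stretches between
# consecutive lines are grouped into one run per sequence (splitting a run
# can never pay since open <= extend <= 0... strictly, since the extra run
# incurs another `open - extend` <= 0).
gapCostForLines <- function(lines, n1, n2, gap) {
    runCost <- function(d) ifelse(d > 0, gap$open + (d - 1) * gap$extend, 0)
    bi <- c(-1L, lines[, 1], n1)
    bj <- c(-1L, lines[, 2], n2)
    sum(runCost(diff(bi) - 1L)) + sum(runCost(diff(bj) - 1L))
}

# Deterministic gapped rows for a line set: between lines, seq1's unmatched
# characters are emitted first (over gaps), then seq2's.
rowsForLines <- function(lines, seq1, seq2) {
    c1 <- strsplit(seq1, "")[[1]]
    c2 <- strsplit(seq2, "")[[1]]
    r1 <- character(0); r2 <- character(0)
    pi <- 0L; pj <- 0L
    emit <- function(ti, tj) {
        d1 <- ti - pi; d2 <- tj - pj
        if (d1 > 0) {
            r1 <<- c(r1, c1[(pi + 1L):ti]); r2 <<- c(r2, rep("-", d1))
        }
        if (d2 > 0) {
            r1 <<- c(r1, rep("-", d2)); r2 <<- c(r2, c2[(pj + 1L):tj])
        }
        pi <<- ti; pj <<- tj
    }
    if (nrow(lines) > 0L) {
        for (r in seq_len(nrow(lines))) {
            emit(lines[r, 1], lines[r, 2])
            r1 <- c(r1, c1[lines[r, 1] + 1L])
            r2 <- c(r2, c2[lines[r, 2] + 1L])
            pi <- lines[r, 1] + 1L; pj <- lines[r, 2] + 1L
        }
    }
    emit(length(c1), length(c2))
    c(paste(r1, collapse = ""), paste(r2, collapse = ""))
}
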