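# Maximum weighted matching on the interaction graph over active lines:
# the source of the valid (lower-bound) solution.
#
# Candidate edges are undirected, with endpoints identified by arbitrary
# string keys (here: "i j" line keys). Edges of non-positive weight are
# dropped up front - they can never improve a matching.

prepareEdges <- function(edges) {
    stopifnot(is.data.frame(edges),
              all(c("end1", "end2", "weight") %in% names(edges)))
    if (nrow(edges) > 0L && any(edges$end1 == edges$end2))
        stop("candidate edge endpoints must be distinct")
    edges <- edges[edges$weight > 0, , drop = FALSE]
    if (nrow(edges) == 0L) return(edges)
    # canonical endpoint order inside each edge, then the deterministic
    # global sort: weight descending, then endpoint keys ascending
    swap <- edges$end1 > edges$end2
    tmp <- edges$end1[swap]
    edges$end1[swap] <- edges$end2[swap]
    edges$end2[swap] <- tmp
    edges <- edges[order(-edges$weight, edges$end1, edges$end2), ,
                   drop = FALSE]
    rownames(edges) <- NULL
    edges
}

# best matching among a small edge set by exhaustive recursion;
# returns indices into `edges`. Deterministic: the first subset found in
# enumeration order wins ties.
bestSubset <- function(edges) {
    n <- nrow(edges)
    best <- list(weight = 0, idx = integer(0))
    recurse <- function(k, used, idx, w) {
        if (w > best$weight + 1e-12) best <<- list(weight = w, idx = idx)
        if (k > n) return()
        for (r in k:n) {
            e1 <- edges$end1[r]; e2 <- edges$end2[r]
            if (!(e1 %in% used) && !(e2 %in% used))
                recurse(r + 1L, c(used, e1, e2), c(idx, r),
                        w + edges$weight[r])
        }
    }
    recurse(1L, character(0), integer(0), 0)
    best
}

#' Greedy maximum weighted matching with look-ahead
#'
#' Edges are sorted by weight (descending; ties by endpoint keys). The
#' heaviest `k` remaining edges form a window on which an exhaustive search
#' finds the maximum-weight mutually compatible subset; that subset is
#' committed, all edges incident to its endpoints are removed, and the
#' process repeats until no edges remain. With `k >=` the number of edges a
#' single window covers everything and the result is the exact maximum
#' weighted matching.
#'
#' @param edges data.frame with columns `end1`, `end2` (endpoint keys) and
#'   `weight`; non-positive weights are dropped.
#' @param k look-ahead window size, `>= 1`; default 5.
#' @return List with `selected` (data.frame of committed edges) and
#'   `totalWeight`.
#' @examples
#' path <- data.frame(end1 = c("a", "b", "c"), end2 = c("b", "c", "d"),
#'                    weight = c(2, 3, 2))
#' greedyMatching(path, k = 1)$totalWeight  # 3: pure greedy takes b-c
#' greedyMatching(path, k = 3)$totalWeight  # 4: window search finds a-b + c-d
#' @export
greedyMatching <- function(edges, k = 5L) {
    stopifnot(k >= 1L)
    pool <- prepareEdges(edges)
    selected <- pool[0, , drop = FALSE]
    while (nrow(pool) > 0L) {
        win <- pool[seq_len(min(k, nrow(pool))), , drop = FALSE]
        pick <- bestSubset(win)
        chosen <- win[pick$idx, , drop = FALSE]
        selected <- rbind(selected, chosen)
        usedEnds <- c(chosen$end1, chosen$end2)
        # window edges are consumed either way; other incident edges die too
        inWindow <- seq_len(nrow(win))
        incident <- pool$end1 %in% usedEnds | pool$end2 %in% usedEnds
        drop <- incident
        drop[inWindow] <- TRUE
        pool <- pool[!drop, , drop = FALSE]
    }
    rownames(selected) <- NULL
    list(selected = selected, totalWeight = sum(selected$weight))
}

#' Exact maximum weighted matching by exhaustive search
#'
#' Brute-force oracle over all matchings; guarded to at most 20 edges. Used
#' as the reference the greedy heuristic is compared against.
#'
#' @param edges data.frame with `end1`, `end2`, `weight`.
#' @return List with `selected` and `totalWeight`.
#' @export
exactMatching <- function(edges) {
    pool <- prepareEdges(edges)
    if (nrow(pool) > 20L)
        stop("exactMatching is an exhaustive oracle; refusing ",
             nrow(pool), " > 20 edges")
    pick <- bestSubset(pool)
    selected <- pool[pick$idx, , drop = FALSE]
    rownames(selected) <- NULL
    list(selected = selected, totalWeight = pick$weight)
}
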