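# The Lagrange iteration engine.
#
# The mutuality constraint y(l,m) = y(m,l) is dualised with one multiplier
# per directed edge. In the relaxed problem each line may claim its best
# outgoing interaction edge independently; the adjusted weight of directed
# edge (l,m) is w_lm + lambda(l,m) - lambda(m,l). On any feasible (mutual)
# solution the lambda terms cancel, so for every lambda the relaxed optimum
# upper-bounds the valid optimum. The subgradient of the dual at lambda has
# component y(l,m) - y(m,l) per directed edge, and a Held-Karp step
# gamma = mu * (zU_t - zL_best) / ||g||^2 moves the multipliers.

#' Solver parameters
#'
#' @param pmin probability cutoff for building interaction sets from
#'   probability matrices (applied upstream by the pipeline).
#' @param gap a [gapModel()].
#' @param subst 5 x 5 substitution matrix, see [substMatrix()].
#' @param maxIter iteration budget of the Lagrange loop.
#' @param epsilon convergence tolerance on the duality gap `zU - zL`.
#' @param k look-ahead window of the greedy matching.
#' @param mu0 initial subgradient step scale.
#' @param stallLimit consecutive non-improving iterations before `mu` is
#'   halved.
#' @param traceBounds record per-iteration bound trajectories in the result.
#' @return List of class `alignParams`.
#' @export
alignParams <- function(pmin = 1e-3, gap = gapModel(), subst = substMatrix(),
                        maxIter = 500L, epsilon = 1e-4, k = 5L, mu0 = 1,
                        stallLimit = 50L, traceBounds = FALSE) {
    stopifnot(pmin >= 0, pmin < 1, maxIter >= 1L, epsilon >= 0, k >= 1L,
              mu0 > 0, stallLimit >= 1L)
    structure(list(pmin = pmin, gap = gap, subst = subst,
                   maxIter = as.integer(maxIter), epsilon = epsilon,
                   k = as.integer(k), mu0 = mu0,
                   stallLimit = as.integer(stallLimit),
                   traceBounds = isTRUE(traceBounds)),
              class = "alignParams")
}

#' Position-specific score matrix for the relaxed problem
#'
#' The profit of line l is its weight plus the best adjusted outgoing
#' interaction weight if that is positive (a line may always decline
#' structure): `S(i,j) = w_l + max(0, max_m [w_lm + lambda(l,m) -
#' lambda(m,l)])`. Lines without outgoing edges score `w_l`.
#'
#' @param graph an [AlignmentGraph-class].
#' @param lambdaF,lambdaB multipliers for the forward (left-to-right line)
#'   and backward directed edge of each undirected edge row; zero when
#'   omitted.
#' @return n1 x n2 numeric profit matrix.
#' @export
buildScoreMatrix <- function(graph, lambdaF = NULL, lambdaB = NULL) {
    e <- graph@edges
    S <- graph@lineWeights
    if (nrow(e) == 0L) return(S)
    if (is.null(lambdaF)) lambdaF <- numeric(nrow(e))
    if (is.null(lambdaB)) lambdaB <- numeric(nrow(e))
    n2 <- ncol(S)
    adjF <- e$weight + lambdaF - lambdaB   # outgoing from the left line
    adjB <- e$weight + lambdaB - lambdaF   # outgoing from the right line
    cellL <- e$li * n2 + e$lj + 1L         # row-major linearised cell key
    cellR <- e$mi * n2 + e$mj + 1L
    bonus <- c(tapply(c(adjF, adjB), c(cellL, cellR), max))
    keys <- as.integer(names(bonus))
    add <- pmax(0, bonus)
    # keys are i*n2+j+1 -> matrix index [i+1, j+1]
    ii <- (keys - 1L) %/% n2 + 1L
    jj <- (keys - 1L) %% n2 + 1L
    S[cbind(ii, jj)] <- S[cbind(ii, jj)] + add
    S
}

# Which directed edge does each line claim in the relaxed solution?
# For every active line with a positive best adjusted outgoing weight, the
# argmax edge (ties: lowest edge row, forward before backward) is chosen.
# Returns per-edge logicals chosenF / chosenB.
chosenDirectedEdges <- function(graph, lambdaF, lambdaB, lines) {
    e <- graph@edges
    nE <- nrow(e)
    chosenF <- logical(nE); chosenB <- logical(nE)
    if (nE == 0L || nrow(lines) == 0L)
        return(list(chosenF = chosenF, chosenB = chosenB))
    activeKey <- paste(lines[, 1], lines[, 2])
    adjF <- e$weight + lambdaF - lambdaB
    adjB <- e$weight + lambdaB - lambdaF
    keyL <- paste(e$li, e$lj)
    keyR <- paste(e$mi, e$mj)
    # candidate (line, edge, direction) triples: direction 0 = forward
    cand <- data.frame(
        line = c(keyL, keyR),
        edge = c(seq_len(nE), seq_len(nE)),
        dirB = c(rep(FALSE, nE), rep(TRUE, nE)),
        adj = c(adjF, adjB))
    cand <- cand[cand$line %in% activeKey & cand$adj > 1e-12, , drop = FALSE]
    if (nrow(cand) == 0L)
        return(list(chosenF = chosenF, chosenB = chosenB))
    cand <- cand[order(cand$line, -cand$adj, cand$edge, cand$dirB), ,
                 drop = FALSE]
    first <- !duplicated(cand$line)
    pick <- cand[first, , drop = FALSE]
    chosenF[pick$edge[!pick$dirB]] <- TRUE
    chosenB[pick$edge[pick$dirB]] <- TRUE
    list(chosenF = chosenF, chosenB = chosenB)
}

#' Candidate interaction edges over a fixed set of active lines
#'
#' One undirected candidate per graph edge whose two endpoint lines are both
#' active, with the original (multiplier-free) weight. These are the edges
#' the matching step may select for the valid solution.
#'
#' @param lines k x 2 matrix of active lines (0-based).
#' @param graph an [AlignmentGraph-class].
#' @return data.frame `li,lj,mi,mj,weight,end1,end2` (endpoint line keys).
#' @export
extractCandidates <- function(lines, graph) {
    e <- graph@edges
    if (nrow(e) == 0L || nrow(lines) == 0L)
        return(cbind(e[0, , drop = FALSE],
                     data.frame(end1 = character(0), end2 = character(0))))
    activeKey <- paste(lines[, 1], lines[, 2])
    keyL <- paste(e$li, e$lj)
    keyR <- paste(e$mi, e$mj)
    keep <- keyL %in% activeKey & keyR %in% activeKey
    out <- e[keep, , drop = FALSE]
    out$end1 <- keyL[keep]
    out$end2 <- keyR[keep]
    rownames(out) <- NULL
    out
}

# One full Lagrange iteration on a solver state; returns the updated state.
lagrangeStep <- function(st) {
    g <- st$graph
    p <- st$params
    S <- buildScoreMatrix(g, st$lambdaF, st$lambdaB)
    dp <- globalAlign(S, p$gap)
    zU_t <- dp$score
    st$lastRelaxed <- zU_t
    st$zU <- min(st$zU, zU_t)

    # valid solution on the DP's active lines
    lines <- dp$lines
    seqScore <- sum(g@lineWeights[lines + 1L]) +
        gapCostForLines(lines, nchar(g@seq1), nchar(g@seq2), p$gap)
    choice <- chosenDirectedEdges(g, st$lambdaF, st$lambdaB, lines)
    mutual <- choice$chosenF & choice$chosenB
    violated <- xor(choice$chosenF, choice$chosenB)
    # NB: the objective sums over *directed* edges, so a conserved
    # interaction contributes w(l,m) + w(m,l) = p1 + p2; the structure score
    # of a valid solution therefore counts each matched undirected edge
    # twice, matching the per-line bonuses of the relaxed score.
    if (!any(violated)) {
        # relaxed solution is feasible: its mutual edges form the matching
        sel <- g@edges[mutual, , drop = FALSE]
        structScore <- 2 * sum(sel$weight)
        matching <- sel
        zL_t <- seqScore + structScore
    } else {
        cand <- extractCandidates(lines, g)
        mwm <- greedyMatching(
            data.frame(end1 = cand$end1, end2 = cand$end2,
                       weight = cand$weight), k = p$k)
        sel <- merge(cand, mwm$selected[, c("end1", "end2"), drop = FALSE],
                     by = c("end1", "end2"))
        matching <- sel[, c("li", "lj", "mi", "mj", "weight"), drop = FALSE]
        structScore <- 2 * mwm$totalWeight
        zL_t <- seqScore + structScore
    }
    if (zL_t > st$zL + 1e-12) {
        st$zL <- zL_t
        st$stall <- 0L
        rows <- rowsForLines(lines, g@seq1, g@seq2)
        ord <- order(matching$li, matching$lj)
        matching <- matching[ord, , drop = FALSE]
        rownames(matching) <- NULL
        st$best <- list(lines = lines, matching = matching,
                        sequenceScore = seqScore, structureScore = structScore,
                        row1 = rows[1], row2 = rows[2])
    } else {
        st$stall <- st$stall + 1L
    }
    st$t <- st$t + 1L
    if (p$traceBounds)
        st$trace[[length(st$trace) + 1L]] <-
            c(zU = zU_t, zL = zL_t, zUbest = st$zU, zLbest = st$zL)

    if (st$zU - st$zL <= p$epsilon || !any(violated)) {
        st$converged <- TRUE
        return(st)
    }
    # subgradient update
    gF <- as.numeric(choice$chosenF) - as.numeric(choice$chosenB)
    normSq <- 2 * sum(violated)
    gamma <- st$mu * (zU_t - st$zL) / normSq
    if (!is.finite(gamma) || gamma <= 0) gamma <- st$mu  # pre-first-zL guard

    st$lambdaF <- st$lambdaF - gamma * gF
    st$lambdaB <- st$lambdaB + gamma * gF
    if (st$stall >= p$stallLimit) {
        st$mu <- st$mu / 2
        st$stall <- 0L
    }
    st
}

lagrangeInit <- function(graph, params) {
    nE <- nrow(graph@edges)
    list(graph = graph, params = params,
         lambdaF = numeric(nE), lambdaB = numeric(nE),
         zU = Inf, zL = -Inf, best = NULL, lastRelaxed = NA_real_,
         mu = params$mu0, stall = 0L, t = 0L, converged = FALSE,
         trace = list())
}

finalizeState <- function(st) {
    g <- st$graph
    tr <- if (length(st$trace))
        as.data.frame(do.call(rbind, st$trace))
    else data.frame(zU = numeric(0), zL = numeric(0),
                    zUbest = numeric(0), zLbest = numeric(0))
    b <- st$best
    new("StructuralAlignment",
        id1 = g@id1, id2 = g@id2, row1 = b$row1, row2 = b$row2,
        lines = b$lines, matching = b$matching,
        sequenceScore = b$sequenceScore, structureScore = b$structureScore,
        zUpper = st$zU, zLower = st$zL, iterations = st$t,
        converged = st$converged, trace = tr)
}

#' Solve one pairwise sequence-structure alignment
#'
#' Iterates the Lagrange loop: build the adjusted position-specific score
#' matrix, solve the relaxed problem by global alignment (upper bound), find
#' a valid solution by matching interactions over the active lines (lower
#' bound), then update the multipliers by a subgradient step. Stops when the
#' duality gap is at most `epsilon` (a gap of zero certifies optimality),
#' when the relaxed solution is itself feasible, or at the iteration budget.
#' The best valid alignment over all iterations is reported.
#'
#' @param seq1,seq2 RNA sequences (character scalars).
#' @param s1,s2 interaction sets (data.frames `i`, `j`, `p`).
#' @param params an [alignParams()].
#' @param id1,id2 sequence identifiers.
#' @return A [StructuralAlignment-class] with bound slots filled in.
#' @examples
#' s <- pairsToInteractions(data.frame(i = 0, j = 7))
#' res <- solvePairwise("GGAAAACC", "GGAAAACC", s, s)
#' totalScore(res)
#' @export
solvePairwise <- function(seq1, seq2, s1, s2, params = alignParams(),
                          id1 = "seq1", id2 = "seq2") {
    if (nchar(seq1) == 0L || nchar(seq2) == 0L)
        stop("cannot align an empty sequence")
    graph <- buildAlignmentGraph(seq1, seq2, s1, s2, params$subst, id1, id2)
    st <- lagrangeInit(graph, params)
    if (nrow(graph@edges) == 0L) {
        # no dualised constraints exist: one DP solve is optimal
        st <- lagrangeStep(st)
        return(finalizeState(st))
    }
    while (!st$converged && st$t < params$maxIter)
        st <- lagrangeStep(st)
    finalizeState(st)
}

#' All-pairs sequence-structure alignment
#'
#' Solves all `s*(s-1)/2` sequence pairs in canonical order (i < j). The
#' Lagrange iteration advances in lock-step batches across all pairs; pairs
#' that converge drop out of subsequent batches. Results are independent of
#' the worker count.
#'
#' @param seqs named character vector of `s >= 2` sequences.
#' @param structures list of per-sequence interaction sets, parallel to
#'   `seqs`.
#' @param params an [alignParams()].
#' @param workers forked worker processes used per batch (unix only);
#'   results are identical for any value.
#' @return List of [StructuralAlignment-class], one per pair, in canonical
#'   order; names are `"id1|id2"`.
#' @export
allPairs <- function(seqs, structures, params = alignParams(), workers = 1L) {
    s <- length(seqs)
    if (s < 2L) stop("need at least 2 sequences, got ", s)
    stopifnot(length(structures) == s)
    ids <- names(seqs)
    if (is.null(ids)) ids <- paste0("seq", seq_len(s))
    combos <- utils::combn(s, 2)
    states <- lapply(seq_len(ncol(combos)), function(k) {
        a <- combos[1, k]; b <- combos[2, k]
        graph <- buildAlignmentGraph(seqs[[a]], seqs[[b]],
                                     structures[[a]], structures[[b]],
                                     params$subst, ids[a], ids[b])
        lagrangeInit(graph, params)
    })
    advance <- function(st) {
        if (st$converged || st$t >= params$maxIter) return(st)
        lagrangeStep(st)
    }
    active <- function() vapply(states, function(st)
        !st$converged && st$t < params$maxIter, logical(1))
    # degenerate pairs (no edges) still get their single DP solve via one step
    while (any(idx <- active())) {
        run <- which(idx)
        stepped <- if (workers > 1L && .Platform$OS.type == "unix")
            parallel::mclapply(states[run], advance, mc.cores = workers)
        else lapply(states[run], advance)
        states[run] <- stepped
    }
    res <- lapply(states, finalizeState)
    names(res) <- paste(ids[combos[1, ]], ids[combos[2, ]], sep = "|")
    res
}
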