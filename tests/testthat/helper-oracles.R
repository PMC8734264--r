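# Independent brute-force oracles. These deliberately re-derive everything
# from first principles (enumeration) and share no code with the package
# solver paths they are used to check.

# all monotone line sets (global alignments) of an n1 x n2 grid, as a list
# of k x 2 0-based matrices including the empty set
enumerateLineSets <- function(n1, n2) {
    out <- list(matrix(integer(0), 0, 2))
    maxk <- min(n1, n2)
    if (maxk == 0L) return(out)
    for (k in seq_len(maxk)) {
        rows <- utils::combn(n1, k) - 1L
        cols <- utils::combn(n2, k) - 1L
        for (a in seq_len(ncol(rows))) {
            for (b in seq_len(ncol(cols))) {
                out[[length(out) + 1L]] <- cbind(rows[, a], cols[, b])
            }
        }
    }
    out
}

# affine gap cost of a line set, grouping unaligned stretches into one run
# per sequence per segment (optimal since open <= extend <= 0)
oracleGapCost <- function(lines, n1, n2, open, extend) {
    run <- function(d) if (d > 0) open + (d - 1) * extend else 0
    bi <- c(-1L, lines[, 1], n1)
    bj <- c(-1L, lines[, 2], n2)
    sum(vapply(diff(bi) - 1L, run, numeric(1))) +
        sum(vapply(diff(bj) - 1L, run, numeric(1)))
}

# brute-force optimal global alignment score for a profit matrix
oracleAlignScore <- function(S, open, extend) {
    n1 <- nrow(S); n2 <- ncol(S)
    best <- -Inf
    for (ls in enumerateLineSets(n1, n2)) {
        sc <- sum(S[ls + 1L]) + oracleGapCost(ls, n1, n2, open, extend)
        if (sc > best) best <- sc
    }
    best
}

# brute-force maximum weighted matching value over an undirected edge list
# given as data.frame(end1, end2, weight)
oracleMatchingWeight <- function(edges) {
    n <- nrow(edges)
    if (n == 0L) return(0)
    best <- 0
    rec <- function(k, used, w) {
        if (w > best) best <<- w
        if (k > n) return()
        for (r in k:n) {
            if (!(edges$end1[r] %in% used) && !(edges$end2[r] %in% used))
                rec(r + 1L, c(used, edges$end1[r], edges$end2[r]),
                    w + edges$weight[r])
        }
    }
    rec(1L, character(0), 0)
    best
}

# exhaustive optimum z* of the full structural alignment problem:
# max over all monotone line sets of sequence score + gap cost + the
# directed-sum structure score (each conserved interaction counts both
# directed edges, i.e. twice its undirected weight)
oracleStructuralOptimum <- function(W, edges, n1, n2, open, extend) {
    best <- -Inf
    for (ls in enumerateLineSets(n1, n2)) {
        seqScore <- sum(W[ls + 1L]) + oracleGapCost(ls, n1, n2, open, extend)
        sc <- seqScore
        if (nrow(edges) > 0L && nrow(ls) > 0L) {
            key <- paste(ls[, 1], ls[, 2])
            keep <- paste(edges$li, edges$lj) %in% key &
                paste(edges$mi, edges$mj) %in% key
            if (any(keep)) {
                cand <- data.frame(
                    end1 = paste(edges$li, edges$lj)[keep],
                    end2 = paste(edges$mi, edges$mj)[keep],
                    weight = edges$weight[keep])
                sc <- sc + 2 * oracleMatchingWeight(cand)
            }
        }
        if (sc > best) best <- sc
    }
    best
}

# random small structural instance for sandwich tests
randomInstance <- function(maxLen = 6L, maxInter = 3L) {
    n1 <- sample(4:maxLen, 1)
    n2 <- sample(4:maxLen, 1)
    randSeq <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                        replace = TRUE), collapse = "")
    randInter <- function(n) {
        k <- sample(0:maxInter, 1)
        out <- data.frame(i = integer(0), j = integer(0), p = numeric(0))
        tries <- 0
        while (nrow(out) < k && tries < 50) {
            tries <- tries + 1
            ij <- sort(sample(0:(n - 1), 2))
            if (any(out$i == ij[1] | out$j == ij[1] |
                    out$i == ij[2] | out$j == ij[2])) next
            out <- rbind(out, data.frame(i = ij[1], j = ij[2],
                                         p = round(stats::runif(1, 0.1, 1), 3)))
        }
        out[order(out$i), , drop = FALSE]
    }
    list(seq1 = randSeq(n1), seq2 = randSeq(n2),
         s1 = randInter(n1), s2 = randInter(n2), n1 = n1, n2 = n2)
}
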