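# The alignment graph: line weights from a substitution scheme, interaction
# edges from the cross product of the two interaction sets.

#' Build the alignment graph for one sequence pair
#'
#' Line weights are the substitution scores of the two nucleotides (the
#' dense n1 x n2 matrix). For every combination of an interaction (i,i',p1)
#' of sequence 1 with an interaction (j,j',p2) of sequence 2, an undirected
#' interaction edge joins the "left partners" line (i,j) with the "right
#' partners" line (i',j'), with weight (p1+p2)/2; it stands for the two
#' directed edges (l,m) and (m,l) of equal weight. The crossing pairing
#' (i,j')/(i',j) is never created.
#'
#' @param seq1,seq2 RNA sequences (character scalars over `A,C,G,U,N`).
#' @param s1,s2 interaction sets (data.frames `i`, `j`, `p`), e.g. from
#'   [pairsToInteractions()] or [thresholdInteractions()].
#' @param subst 5 x 5 substitution matrix, see [substMatrix()].
#' @param id1,id2 sequence identifiers.
#' @return An [AlignmentGraph-class].
#' @examples
#' s1 <- pairsToInteractions(data.frame(i = 0, j = 5))
#' g <- buildAlignmentGraph("GGAACC", "GGAACC", s1, s1)
#' numInteractionEdges(g)  # 2: one undirected edge, both directions
#' @export
buildAlignmentGraph <- function(seq1, seq2, s1, s2,
                                subst = substMatrix(),
                                id1 = "seq1", id2 = "seq2") {
    n1 <- nchar(seq1); n2 <- nchar(seq2)
    stopifnot(n1 >= 1, n2 >= 1)
    validateInteractionSet(s1, n1)
    validateInteractionSet(s2, n2)
    c1 <- strsplit(seq1, "")[[1]]
    c2 <- strsplit(seq2, "")[[1]]
    W <- subst[c1, c2, drop = FALSE]
    dimnames(W) <- NULL
    if (nrow(s1) > 0L && nrow(s2) > 0L) {
        g <- expand.grid(a = seq_len(nrow(s1)), b = seq_len(nrow(s2)))
        edges <- data.frame(
            li = s1$i[g$a], lj = s2$i[g$b],
            mi = s1$j[g$a], mj = s2$j[g$b],
            weight = (s1$p[g$a] + s2$p[g$b]) / 2)
        edges <- edges[order(edges$li, edges$lj, edges$mi, edges$mj), ,
                       drop = FALSE]
        rownames(edges) <- NULL
    } else {
        edges <- data.frame(li = integer(0), lj = integer(0),
                            mi = integer(0), mj = integer(0),
                            weight = numeric(0))
    }
    new("AlignmentGraph", id1 = id1, id2 = id2, seq1 = seq1, seq2 = seq2,
        lineWeights = W, edges = edges)
}

#' Validate a structural alignment against the ILP constraints
#'
#' Checks the four feasibility constraints of the alignment model:
#' 1. active lines are conflict-free (no two lines cross or share a node);
#' 2. each line is incident to at most one matched interaction edge;
#' 3. a matched edge's endpoint lines are both active;
#' 4. interaction edges are mutual (the reverse edge is selected with its
#'    twin) and exist in the graph.
#'
#' Validation reports all violations rather than stopping at the first.
#'
#' @param aln a [StructuralAlignment-class].
#' @param graph the [AlignmentGraph-class] the alignment refers to.
#' @return List with `valid` (logical) and `violations` (character vector).
#' @export
validateAlignment <- function(aln, graph) {
    v <- character(0)
    ln <- aln@lines
    if (nrow(ln) > 0L) {
        ord <- order(ln[, 1])
        s <- ln[ord, , drop = FALSE]
        if (nrow(s) > 1L) {
            bad <- which(diff(s[, 1]) <= 0 | diff(s[, 2]) <= 0)
            for (b in bad)
                v <- c(v, sprintf(
                    "constraint 1: lines (%d,%d) and (%d,%d) cross or share a node",
                    s[b, 1], s[b, 2], s[b + 1, 1], s[b + 1, 2]))
        }
        n1 <- nchar(graph@seq1); n2 <- nchar(graph@seq2)
        if (any(ln[, 1] < 0 | ln[, 1] >= n1 | ln[, 2] < 0 | ln[, 2] >= n2))
            v <- c(v, "constraint 1: line endpoint outside the sequence grid")
    }
    m <- aln@matching
    if (nrow(m) > 0L) {
        key <- if (nrow(ln) > 0L) paste(ln[, 1], ln[, 2]) else character(0)
        ends <- c(paste(m$li, m$lj), paste(m$mi, m$mj))
        dup <- unique(ends[duplicated(ends)])
        for (d in dup)
            v <- c(v, sprintf(
                "constraint 2: line (%s) is incident to more than one matched edge",
                gsub(" ", ",", d)))
        inactive <- setdiff(unique(ends), key)
        for (d in inactive)
            v <- c(v, sprintf(
                "constraint 3: matched edge endpoint line (%s) is not active",
                gsub(" ", ",", d)))
        ge <- graph@edges
        gkey <- paste(ge$li, ge$lj, ge$mi, ge$mj)
        mkey <- paste(m$li, m$lj, m$mi, m$mj)
        missing <- setdiff(mkey, gkey)
        for (d in missing)
            v <- c(v, sprintf(
                "constraint 4: matched edge (%s) has no mutual twin in the graph",
                gsub(" ", ",", d)))
    }
    list(valid = length(v) == 0L, violations = v)
}
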