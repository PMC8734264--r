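test_that("score matrix adds the best positive adjusted outgoing weight", {
    # one hairpin per sequence: edge between line (0,0) and line (5,5)
    s <- pairsToInteractions(data.frame(i = 0L, j = 5L))
    g <- buildAlignmentGraph("GGAACC", "GGAACC", s, s)
    W <- lineWeights(g)
    S0 <- buildScoreMatrix(g)                       # all multipliers zero
    expect_equal(S0[1, 1], W[1, 1] + 1)             # w_lm = 1 at p = 1
    expect_equal(S0[6, 6], W[6, 6] + 1)
    expect_equal(S0[2, 2], W[2, 2])                 # no outgoing edges

    # multipliers shift the forward/backward adjusted weights
    S1 <- buildScoreMatrix(g, lambdaF = 0.25, lambdaB = -0.25)
    expect_equal(S1[1, 1], W[1, 1] + 1.5)           # w + lF - lB
    expect_equal(S1[6, 6], W[6, 6] + 0.5)           # w + lB - lF

    # a negative adjusted weight is declined (max(0, .))
    S2 <- buildScoreMatrix(g, lambdaF = -2, lambdaB = 0)
    expect_equal(S2[1, 1], W[1, 1])
    expect_equal(S2[6, 6], W[6, 6] + 3)
})

test_that("candidate extraction keeps only edges with both endpoint lines active", {
    s1 <- data.frame(i = c(0L, 1L), j = c(5L, 4L), p = c(0.8, 0.6))
    s2 <- data.frame(i = 0L, j = 5L, p = 0.6)
    g <- buildAlignmentGraph("GGAACC", "GGAACC", s1, s2)
    ident <- cbind(0:5, 0:5)
    cand <- extractCandidates(ident, g)
    expect_equal(nrow(cand), 1L)                    # (1,4) line pair inactive
    expect_equal(cand$weight, 0.7)
    expect_equal(nrow(extractCandidates(ident[1:2, ], g)), 0L)
    expect_equal(nrow(extractCandidates(ident[0, , drop = FALSE], g)), 0L)
})

test_that("identical structured sequences converge with coinciding bounds", {
    s <- pairsToInteractions(data.frame(i = c(0L, 1L), j = c(7L, 6L)))
    res <- solvePairwise("GGAAAACC", "GGAAAACC", s, s)
    expect_true(res@converged)
    expect_equal(res@zUpper, res@zLower)
    expect_equal(res@row1, "GGAAAACC")
    expect_equal(res@row2, "GGAAAACC")
    expect_equal(nrow(alignmentMatching(res)), 2L)  # both stem edges matched
    expect_equal(res@structureScore, 4)             # 2 edges x (1+1)/2 x both directions
    expect_equal(totalScore(res), res@zLower)
})

test_that("pairs without interactions converge in one iteration", {
    empty <- data.frame(i = integer(0), j = integer(0), p = numeric(0))
    res <- solvePairwise("GGAACC", "GGACC", empty, empty)
    expect_true(res@converged)
    expect_equal(res@iterations, 1L)
    expect_equal(res@zUpper, res@zLower)
    expect_equal(res@structureScore, 0)
})

test_that("empty sequences are rejected", {
    empty <- data.frame(i = integer(0), j = integer(0), p = numeric(0))
    expect_error(solvePairwise("", "ACGU", empty, empty), "empty sequence")
})

test_that("subgradient step restores mutuality on a single violated pair", {
    # two interactions in seq1 compete for one in seq2: the relaxed solution
    # can pick contradictory directed edges, the update must move lambda
    s1 <- data.frame(i = c(0L, 2L), j = c(8L, 6L), p = c(0.9, 0.8))
    s2 <- data.frame(i = 1L, j = 7L, p = 0.9)
    res <- solvePairwise("GACGAAACC", "ACGAAACCG", s1, s2,
                         alignParams(maxIter = 200, traceBounds = TRUE))
    expect_true(res@zLower <= res@zUpper + 1e-9)
    tr <- res@trace
    expect_true(all(diff(tr$zUbest) <= 1e-9))       # running min
    expect_true(all(diff(tr$zLbest) >= -1e-9))      # running max
})

test_that("bounds sandwich the exhaustive optimum on random instances", {
    set.seed(33)
    for (rep in 1:20) {
        inst <- randomInstance()
        g <- buildAlignmentGraph(inst$seq1, inst$seq2, inst$s1, inst$s2)
        p <- alignParams(maxIter = 150, epsilon = 1e-9, traceBounds = TRUE)
        res <- solvePairwise(inst$seq1, inst$seq2, inst$s1, inst$s2, p)
        zstar <- oracleStructuralOptimum(lineWeights(g), interactionEdges(g),
                                         inst$n1, inst$n2,
                                         p$gap$open, p$gap$extend)
        expect_true(all(res@trace$zLbest <= zstar + 1e-6))
        expect_true(all(res@trace$zUbest >= zstar - 1e-6))
        if (res@converged) expect_equal(res@zLower, zstar, tolerance = 1e-6)
    }
})

test_that("with zero multipliers the relaxed score dominates every valid alignment", {
    set.seed(34)
    for (rep in 1:10) {
        inst <- randomInstance(maxLen = 5L, maxInter = 2L)
        g <- buildAlignmentGraph(inst$seq1, inst$seq2, inst$s1, inst$s2)
        p <- alignParams()
        relaxed <- globalAlign(buildScoreMatrix(g), p$gap)$score
        zstar <- oracleStructuralOptimum(lineWeights(g), interactionEdges(g),
                                         inst$n1, inst$n2,
                                         p$gap$open, p$gap$extend)
        expect_gte(relaxed, zstar - 1e-9)
    }
})

test_that("crossing stems are matched together on a planted pseudoknot", {
    # two mutually crossing stems (a pseudoknot), certain probabilities
    tmpl <- "..((..[[....))..]].."
    ps <- parseDotBracket(tmpl)
    seq <- "GGGCAAGGAAAAGCUUCCAA"
    s <- pairsToInteractions(ps)
    res <- solvePairwise(seq, seq, s, s)
    m <- alignmentMatching(res)
    expect_equal(nrow(m), 4L)                       # all four pairs conserved
    crossing <- outer(seq_len(nrow(m)), seq_len(nrow(m)), function(a, b)
        m$li[a] < m$li[b] & m$li[b] < m$mi[a] & m$mi[a] < m$mi[b])
    expect_true(any(crossing))                      # matched edges cross
})

test_that("all-pairs orchestration is canonical, worker-invariant and complete", {
    fam <- generateFamily(familySpec(nSequences = 3, seed = 5))
    p <- alignParams(maxIter = 60)
    res1 <- allPairs(fam$sequences, fam$structures, p, workers = 1L)
    expect_length(res1, choose(3, 2))
    expect_named(res1, c("seq01|seq02", "seq01|seq03", "seq02|seq03"))
    res4 <- allPairs(fam$sequences, fam$structures, p, workers = 4L)
    expect_equal(res1, res4)
    expect_error(allPairs(fam$sequences[1], fam$structures[1], p),
                 "at least 2")
})
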