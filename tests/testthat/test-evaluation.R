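refAln <- c(s1 = "GGAA-CC", s2 = "GG-AACC")

test_that("SPS is 1 on identity, 0 on disjoint alignments, fractional between", {
    expect_equal(spsScore(refAln, refAln), 1.0)

    # shift one row so no residue pair of the reference is reproduced
    test0 <- c(s1 = "GGAACC------", s2 = "------GGAACC")
    expect_equal(spsScore(test0, refAln), 0)

    # reference with 4 aligned pairs
    ref <- c(a = "ACGU", b = "ACGU")
    test <- c(a = "ACGU--", b = "--ACGU")
    expect_equal(spsScore(test, ref), 0.0)
    test2 <- c(a = "AC-GU", b = "ACG-U")
    # pairs kept: columns 1,2 (A:A, C:C) and column 5 (U:U) -> 3 of 4
    expect_equal(spsScore(test2, ref), 0.75)
})

test_that("SPS validates ids and sequence content", {
    expect_error(spsScore(c(x = "ACGU"), c(y = "ACGU")), "same sequence ids")
    expect_error(spsScore(c(s1 = "AC-GU", s2 = "ACGUA"),
                          c(s1 = "ACGGU", s2 = "ACGUA")),
                 "different sequences")
})

test_that("confusion counts follow the unordered-pair universe", {
    t1 <- list(data.frame(i = 1L, j = 5L))
    r1 <- list(data.frame(i = 1L, j = 5L))
    c1 <- buildConfusion(t1, r1, 6L)
    expect_equal(unclass(c1)[c("tp", "fp", "fn", "tn")],
                 list(tp = 1, fp = 0, fn = 0, tn = choose(6, 2) - 1))

    c2 <- buildConfusion(list(data.frame(i = integer(0), j = integer(0))),
                         list(data.frame(i = 0L, j = 3L)), 5L)
    expect_equal(c2$fn, 1); expect_equal(c2$tp, 0); expect_equal(c2$fp, 0)

    c3 <- buildConfusion(list(data.frame(i = 0L, j = 3L)),
                         list(data.frame(i = 1L, j = 4L)), 6L)
    expect_equal(c3$fp, 1); expect_equal(c3$fn, 1); expect_equal(c3$tp, 0)

    # universe identity: tp+fp+fn+tn = sum C(n_i, 2)
    expect_equal(c3$tp + c3$fp + c3$fn + c3$tn, choose(6, 2))
    expect_error(buildConfusion(list(data.frame(i = 0L, j = 9L)),
                                list(data.frame(i = 0L, j = 1L)), 5L),
                 "out of sequence range")
})

test_that("MCC hits its endpoints and zero conventions", {
    expect_equal(mccScore(list(tp = 10, fp = 0, fn = 0, tn = 100)), 1.0)
    expect_equal(mccScore(list(tp = 0, fp = 5, fn = 5, tn = 0)), -1.0)
    expect_equal(mccScore(list(tp = 1, fp = 1, fn = 1, tn = 1)), 0.0)
    expect_equal(mccScore(list(tp = 0, fp = 0, fn = 3, tn = 10)), 0)  # zero factor
})

test_that("MCC is symmetric under swapping test and reference (fp <-> fn)", {
    set.seed(55)
    for (rep in 1:25) {
        v <- sample(0:20, 4, replace = TRUE)
        a <- mccScore(list(tp = v[1], fp = v[2], fn = v[3], tn = v[4]))
        b <- mccScore(list(tp = v[1], fp = v[3], fn = v[2], tn = v[4]))
        expect_equal(a, b)
    }
})

test_that("consensus projection drops pairs that hit gaps", {
    rows <- c(s1 = "GGAA-CC", s2 = "GG-AACC")
    proj <- projectConsensus(rows, "((...))")
    # s1: columns 1,2,7,6 map to 0,1,5,4 ; pair (1,7)->(0,5), (2,6)->(1,4)
    expect_equal(proj$s1, data.frame(i = 0:1, j = c(5L, 4L)))
    # s2: column 3 is a gap, so the pair using column 2..? both pairs survive
    expect_equal(proj$s2$i, c(0L, 1L))
    proj2 <- projectConsensus(c(x = "A-CG"), "(..)")
    expect_equal(proj2$x, data.frame(i = 0L, j = 2L))
})
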