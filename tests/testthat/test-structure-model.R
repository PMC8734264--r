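test_that("fixed pair sets become certain interactions", {
    expect_equal(pairsToInteractions(data.frame(i = 0L, j = 5L)),
                 data.frame(i = 0L, j = 5L, p = 1.0))
    out <- pairsToInteractions(data.frame(i = c(0L, 1L), j = c(5L, 4L)))
    expect_equal(out$p, c(1, 1))
    expect_equal(nrow(pairsToInteractions(data.frame(i = integer(0),
                                                     j = integer(0)))), 0L)
})

test_that("thresholding keeps exactly the entries above pmin", {
    m <- matrix(0, 6, 6)
    m[1, 6] <- m[6, 1] <- 0.9
    m[2, 5] <- m[5, 2] <- 5e-4
    x <- bppm(m)
    expect_equal(thresholdInteractions(x, 1e-3),
                 data.frame(i = 0L, j = 5L, p = 0.9))
    expect_equal(nrow(thresholdInteractions(x, 0)), 2L)
    expect_equal(nrow(thresholdInteractions(bppm(matrix(0, 4, 4)), 0)), 0L)
})

test_that("thresholding is monotone in pmin and idempotent on certain pairs", {
    set.seed(11)
    for (rep in 1:20) {
        n <- sample(5:10, 1)
        m <- matrix(0, n, n)
        k <- sample(1:4, 1)
        for (x in seq_len(k)) {
            ij <- sort(sample(seq_len(n), 2))
            v <- round(stats::runif(1), 3)
            m[ij[1], ij[2]] <- m[ij[2], ij[1]] <- v
        }
        m <- m / max(1, max(rowSums(m)))    # keep row sums legal
        b <- bppm(m)
        lo <- thresholdInteractions(b, 0.1)
        hi <- thresholdInteractions(b, 0.5)
        expect_true(all(paste(hi$i, hi$j) %in% paste(lo$i, lo$j)))
    }
    cert <- pairsToInteractions(data.frame(i = c(0L, 2L), j = c(9L, 7L)))
    # certain interactions survive any threshold below 1
    mat <- matrix(0, 10, 10)
    mat[cbind(cert$i + 1, cert$j + 1)] <- 1
    mat[cbind(cert$j + 1, cert$i + 1)] <- 1
    expect_equal(thresholdInteractions(bppm(mat), 0.999), cert)
})

test_that("dot-bracket ingestion applies the minimum-hairpin and N filters", {
    # (1,4) spans j-i=3 < 4: rejected; (0,5) kept
    out <- structureFromDotBracket("((..))", "GGAACC")
    expect_equal(out, data.frame(i = 0L, j = 5L, p = 1.0))
    # N never participates
    out2 <- structureFromDotBracket("(....)", "NAAAAC")
    expect_equal(nrow(out2), 0L)
})

test_that("row-sum validity rejects over-committed probability matrices", {
    m <- matrix(0, 4, 4)
    m[1, 3] <- m[3, 1] <- 0.7
    m[1, 4] <- m[4, 1] <- 0.6   # row 1 sums to 1.3
    expect_error(bppm(m), "row sums")
})

test_that("external folding harvests a stub tool's dot-plot", {
    stub <- withr::local_tempfile(fileext = ".sh")
    writeLines(c("#!/bin/sh",
                 "cat > /dev/null",
                 "printf '%s\\n' '%!PS' '1 5 0.5 ubox' '2 4 0.9 lbox' > seq_dp.ps"),
               stub)
    Sys.chmod(stub, "0755")
    m <- probMatrix(foldExternal("ACGUA", "seq", stub))
    expect_equal(m[1, 5], 0.25)   # ubox value is sqrt(p)
    expect_equal(m[2, 4], 0)      # lbox ignored
})

test_that("a missing folding executable gives an actionable error", {
    expect_error(foldExternal("ACGU", "s", "/no/such/binary-xyz"),
                 "structure annotations")
})

test_that("a failing folding executable propagates its stderr", {
    stub <- withr::local_tempfile(fileext = ".sh")
    writeLines(c("#!/bin/sh", "echo boom >&2", "exit 3"), stub)
    Sys.chmod(stub, "0755")
    expect_error(foldExternal("ACGU", "s", stub), "boom")
})
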