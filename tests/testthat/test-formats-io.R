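test_that("FASTA reading normalises case and DNA-style T, keeps first header token", {
    fa <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">s1 trailing description", "acgt", ">s2", "GGNCC"), fa)
    seqs <- readRnaFasta(fa)
    expect_identical(seqs, c(s1 = "ACGU", s2 = "GGNCC"))
})

test_that("FASTA reading rejects residues outside the RNA alphabet, with position", {
    fa <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">s1", "ACXU"), fa)
    expect_error(readRnaFasta(fa), "invalid residue 'X' at 3")
    fa2 <- withr::local_tempfile(fileext = ".fa")
    writeLines(character(0), fa2)
    expect_error(readRnaFasta(fa2), "no sequences")
})

test_that("dot-bracket parsing matches nested pairs and crossing tiers", {
    expect_equal(parseDotBracket("((..))"),
                 data.frame(i = 0:1, j = c(5L, 4L)))
    # two tiers crossing = pseudoknot
    expect_equal(parseDotBracket("([)]"),
                 data.frame(i = 0:1, j = 2:3))
    # letter tiers
    expect_equal(parseDotBracket(".A.a."),
                 data.frame(i = 1L, j = 3L))
})

test_that("dot-bracket parsing reports unbalanced tiers and length mismatch", {
    expect_error(parseDotBracket("((."), "unbalanced")
    expect_error(parseDotBracket(".))"), "unbalanced")
    expect_error(parseDotBracket("([.)", 4), "unbalanced")
    expect_error(parseDotBracket("....", 5), "length")
})

test_that("dot-bracket round-trip preserves pair sets, nested and crossing", {
    cases <- list("((..))", "([)]", "..((..[[..))..]].", ".....",
                  "((..((..))..)).<.>")
    for (s in cases) {
        ps <- parseDotBracket(s)
        again <- parseDotBracket(renderDotBracket(ps, nchar(s)), nchar(s))
        expect_equal(again, ps, info = s)
    }
    # non-crossing sets render back to the identical string
    expect_identical(renderDotBracket(parseDotBracket("((..))"), 6), "((..))")
})

test_that("plain3col BPPM reading fills a symmetric matrix and validates", {
    f <- withr::local_tempfile(fileext = ".txt")
    writeLines("1 6 0.9", f)
    m <- probMatrix(readBppm(f, "plain3col", 6))
    expect_equal(m[1, 6], 0.9)
    expect_equal(m[6, 1], 0.9)
    expect_equal(sum(m), 1.8)

    writeLines("1 6 1.5", f)
    expect_error(readBppm(f, "plain3col", 6), "probability out of range")
    writeLines("1 9 0.5", f)
    expect_error(readBppm(f, "plain3col", 6), "out of range")
})

test_that("vienna dot-plot reading squares ubox entries and ignores lbox", {
    f <- withr::local_tempfile(fileext = ".ps")
    writeLines(c("%!PS", "/ubox {} def", "1 6 0.3 ubox", "2 5 0.9 lbox",
                 "showpage"), f)
    m <- probMatrix(readBppm(f, "vienna_dp", 6))
    expect_equal(m[1, 6], 0.09)
    expect_equal(m[2, 5], 0)
})

test_that("plain3col BPPM round-trips losslessly", {
    mat <- matrix(0, 7, 7)
    mat[1, 6] <- mat[6, 1] <- 0.875
    mat[2, 5] <- mat[5, 2] <- 0.125
    x <- bppm(mat)
    f <- withr::local_tempfile(fileext = ".bppm")
    writeBppm(x, f)
    expect_equal(probMatrix(readBppm(f, "plain3col", 7)), mat)
})

test_that("T-Coffee library writer emits one block per pair and re-parses", {
    s <- pairsToInteractions(data.frame(i = 0L, j = 5L))
    seqs <- c(a = "GGAACC", b = "GGAACC")
    res <- list(solvePairwise(seqs[[1]], seqs[[2]], s, s,
                              id1 = "a", id2 = "b"))
    f <- withr::local_tempfile(fileext = ".lib")
    writeTcoffeeLibrary(res, seqs, f)
    lines <- readLines(f)
    expect_identical(lines[1], "! TC_LIB_FORMAT_01")
    expect_identical(lines[2], "2")
    expect_identical(sum(grepl("^#", lines)), 1L)

    lib <- readTcoffeeLibrary(f)
    expect_identical(lib$seqs, seqs)
    blk <- lib$pairs[[1]]
    expect_equal(blk$pos1, activeLines(res[[1]])[, 1] + 1L)
    expect_equal(blk$pos2, activeLines(res[[1]])[, 2] + 1L)
    expect_true(all(blk$weight >= 1 & blk$weight <= 100))
})

test_that("T-Coffee writer rejects empty results and unknown ids", {
    expect_error(writeTcoffeeLibrary(list(), c(a = "ACGU"), tempfile()),
                 "nothing to write")
    s <- pairsToInteractions(data.frame(i = integer(0), j = integer(0)))
    res <- list(solvePairwise("ACGU", "ACGU", s, s, id1 = "x", id2 = "y"))
    expect_error(writeTcoffeeLibrary(res, c(a = "ACGU", b = "ACGU"),
                                     tempfile()),
                 "unknown sequence id")
})

test_that("MAFFT pair output is exactly three lines per pair", {
    empty <- data.frame(i = integer(0), j = integer(0), p = numeric(0))
    seqs <- c(a = "GGAACC", b = "GGACC", c = "GGAAC")
    res <- allPairs(seqs, list(empty, empty, empty))
    f <- withr::local_tempfile()
    writeMafftPairs(res, f)
    lines <- readLines(f)
    expect_length(lines, 3L * choose(3, 2))
    headers <- lines[seq(1, length(lines), 3)]
    expect_true(all(startsWith(headers, ">")))
    rows1 <- lines[seq(2, length(lines), 3)]
    rows2 <- lines[seq(3, length(lines), 3)]
    expect_equal(nchar(rows1), nchar(rows2))
})

test_that("aligned FASTA writer emits four lines for one pair only", {
    empty <- data.frame(i = integer(0), j = integer(0), p = numeric(0))
    res <- solvePairwise("ACGU", "ACGU", empty, empty, id1 = "u", id2 = "v")
    f <- withr::local_tempfile(fileext = ".afa")
    writeAlignedFasta(list(res), f)
    lines <- readLines(f)
    expect_identical(lines, c(">u", "ACGU", ">v", "ACGU"))
    expect_error(writeAlignedFasta(list(res, res), tempfile()),
                 "exactly one")
})

test_that("structure annotation files are accepted in both layouts", {
    seqs <- c(s1 = "GGAAACC", s2 = "GGAAACC")
    bare <- withr::local_tempfile()
    writeLines(c("((...))", "(.....)"), bare)
    ps <- readDotBracketFile(bare, seqs)
    expect_equal(ps$s1, data.frame(i = 0:1, j = c(6L, 5L)))
    expect_equal(ps$s2, data.frame(i = 0L, j = 6L))

    vienna <- withr::local_tempfile()
    writeLines(c(">s1", "GGAAACC", "((...))",
                 ">s2", "GGAAACC", "(.....)"), vienna)
    expect_equal(readDotBracketFile(vienna, seqs), ps)
})
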