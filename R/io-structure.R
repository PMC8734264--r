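# Dot-bracket and base-pair-probability-matrix I/O.
#
# The extended dot-bracket alphabet supports pseudoknots: each bracket tier
# is matched independently by its own stack, and pairs from different tiers
# may cross. Tier order follows the page convention (), [], {}, <>, Aa..Zz.

bracketTiers <- function() {
    open <- c("(", "[", "{", "<", LETTERS)
    close <- c(")", "]", "}", ">", letters)
    list(open = open, close = close)
}

#' Parse a dot-bracket string into a set of base pairs
#'
#' Each bracket tier is matched with its own stack, so pairs of different
#' tiers may cross: `"([)]"` yields the crossing (pseudoknotted) pairs
#' (0,2) and (1,3). Dots (and any unpaired annotation) are ignored.
#'
#' @param text dot-bracket string; brackets from `()`, `[]`, `{}`, `<>` and
#'   `Aa`..`Zz`; `.` marks unpaired positions.
#' @param n expected sequence length; `nchar(text)` must equal `n`.
#' @return data.frame with 0-based integer columns `i < j`, ordered by `i`.
#' @examples
#' parseDotBracket("((..))", 6)
#' parseDotBracket("([)]", 4)   # crossing pairs
#' @export
parseDotBracket <- function(text, n = nchar(text)) {
    if (nchar(text) != n)
        stop(sprintf("structure length %d does not match sequence length %d",
                     nchar(text), n))
    chars <- strsplit(text, "")[[1]]
    tiers <- bracketTiers()
    i <- integer(0); j <- integer(0)
    for (t in seq_along(tiers$open)) {
        op <- tiers$open[t]; cl <- tiers$close[t]
        if (!any(chars == op | chars == cl)) next
        stack <- integer(0)
        for (pos in seq_len(n)) {
            if (chars[pos] == op) {
                stack <- c(stack, pos)
            } else if (chars[pos] == cl) {
                if (length(stack) == 0L)
                    stop(sprintf("unbalanced bracket '%s' (tier %d) at %d",
                                 cl, t, pos))
                i <- c(i, stack[length(stack)] - 1L)
                j <- c(j, pos - 1L)
                stack <- stack[-length(stack)]
            }
        }
        if (length(stack) > 0L)
            stop(sprintf("unbalanced bracket '%s' (tier %d) at %d",
                         op, t, stack[length(stack)]))
    }
    ps <- data.frame(i = as.integer(i), j = as.integer(j))
    ps <- ps[order(ps$i, ps$j), , drop = FALSE]
    rownames(ps) <- NULL
    validatePairSet(ps, n)
    ps
}

validatePairSet <- function(ps, n = NULL) {
    stopifnot(is.data.frame(ps), all(c("i", "j") %in% names(ps)))
    if (nrow(ps) == 0L) return(invisible(ps))
    if (any(ps$i >= ps$j)) stop("pairs must satisfy i < j")
    pos <- c(ps$i, ps$j)
    if (anyDuplicated(pos)) stop("a position occurs in more than one pair")
    if (!is.null(n) && (any(pos < 0) || any(pos >= n)))
        stop("pair position out of range [0, n)")
    invisible(ps)
}

#' Render a pair set as an extended dot-bracket string
#'
#' Pairs are assigned greedily to the first tier in which they nest with the
#' tier's previously placed pairs; crossing pairs therefore spill into
#' higher tiers. `parseDotBracket(renderDotBracket(ps, n), n)` recovers the
#' same pair set (tier assignment of crossing pairs may differ from an
#' original annotation).
#'
#' @param ps data.frame of 0-based pairs (`i < j`).
#' @param n sequence length.
#' @return A dot-bracket string of length `n`.
#' @export
renderDotBracket <- function(ps, n) {
    validatePairSet(ps, n)
    tiers <- bracketTiers()
    out <- rep(".", n)
    placed <- list()
    ord <- order(ps$i)
    for (r in ord) {
        a <- ps$i[r]; b <- ps$j[r]
        t <- 1L
        repeat {
            if (t > length(tiers$open)) stop("too many crossing tiers")
            prior <- placed[[as.character(t)]]
            crosses <- FALSE
            if (!is.null(prior) && nrow(prior) > 0L)
                crosses <- any((prior$i < a & a < prior$j & prior$j < b) |
                               (a < prior$i & prior$i < b & b < prior$j))
            if (!crosses) break
            t <- t + 1L
        }
        placed[[as.character(t)]] <-
            rbind(placed[[as.character(t)]], data.frame(i = a, j = b))
        out[a + 1L] <- tiers$open[t]
        out[b + 1L] <- tiers$close[t]
    }
    paste(out, collapse = "")
}

#' Read per-sequence dot-bracket annotations
#'
#' Two layouts are accepted: a bare file with one structure line per
#' sequence (in input order), or a FASTA-like "vienna" layout where each
#' record has three lines: `>id`, sequence, structure.
#'
#' @param path path to the annotation file.
#' @param seqs named character vector of sequences the annotations belong to.
#' @return Named list of pair-set data.frames, one per sequence.
#' @export
readDotBracketFile <- function(path, seqs) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("no structure annotations in ", path)
    if (startsWith(lines[1], ">")) {
        if (length(lines) %% 3L != 0L)
            stop("vienna-style structure file must have 3 lines per record")
        ids <- sub("^>", "", vapply(strsplit(lines[seq(1, length(lines), 3)],
                                             "[ \t]+"), `[`, character(1), 1L))
        structs <- trimws(lines[seq(3, length(lines), 3)])
        names(structs) <- ids
        missing <- setdiff(names(seqs), ids)
        if (length(missing))
            stop("no structure annotation for sequence(s): ",
                 paste(missing, collapse = ", "))
        structs <- structs[names(seqs)]
    } else {
        if (length(lines) != length(seqs))
            stop(sprintf("found %d structure lines for %d sequences",
                         length(lines), length(seqs)))
        structs <- stats::setNames(trimws(lines), names(seqs))
    }
    mapply(function(s, q) parseDotBracket(s, nchar(q)),
           structs, seqs, SIMPLIFY = FALSE)
}

#' Read a base-pair probability matrix
#'
#' Two dialects are supported. `plain3col` is a plain-text table of rows
#' `i j p` with 1-based positions `i < j` and `p` in (0,1]. `vienna_dp` is a
#' ViennaRNA dot-plot PostScript file, from which only `ubox` records are
#' read; their third field is the *square root* of the pairing probability,
#' so values are squared on input. Unlisted entries are zero and the result
#' is symmetric.
#'
#' @param path input file.
#' @param dialect `"plain3col"` or `"vienna_dp"`.
#' @param n sequence length (matrix dimension).
#' @return A [BasePairProbMatrix-class].
#' @export
readBppm <- function(path, dialect = c("plain3col", "vienna_dp"), n) {
    dialect <- match.arg(dialect)
    lines <- readLines(path)
    m <- matrix(0, n, n)
    fill <- function(i, j, p, what) {
        if (i < 1 || j < 1 || i > n || j > n)
            stop(sprintf("%s index (%d,%d) out of range for n=%d", what, i, j, n))
        if (i >= j) stop(sprintf("%s requires i < j, got (%d,%d)", what, i, j))
        if (p <= 0 || p > 1 + 1e-9)
            stop(sprintf("probability out of range (0,1] at (%d,%d): %g", i, j, p))
        m[i, j] <<- m[j, i] <<- min(p, 1)
    }
    if (dialect == "plain3col") {
        lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
        for (ln in lines) {
            f <- strsplit(trimws(ln), "[ \t]+")[[1]]
            if (length(f) != 3L) stop("malformed plain3col row: ", ln)
            fill(as.integer(f[1]), as.integer(f[2]), as.numeric(f[3]),
                 "plain3col")
        }
    } else {
        hits <- grep("^\\s*\\d+\\s+\\d+\\s+[0-9.eE+-]+\\s+ubox\\s*$", lines,
                     value = TRUE)
        for (ln in hits) {
            f <- strsplit(trimws(ln), "[ \t]+")[[1]]
            fill(as.integer(f[1]), as.integer(f[2]), as.numeric(f[3])^2,
                 "vienna_dp")
        }
    }
    bppm(m)
}

#' Write a base-pair probability matrix as plain 3-column text
#'
#' Emits one `i j p` row (1-based, `i < j`) per non-zero upper-triangle
#' entry; the inverse of `readBppm(..., dialect = "plain3col")`.
#'
#' @param x a [BasePairProbMatrix-class].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writeBppm <- function(x, path) {
    p <- probMatrix(x)
    idx <- which(upper.tri(p) & p > 0, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    writeLines(sprintf("%d %d %.17g", idx[, 1], idx[, 2], p[idx]), path)
    invisible(path)
}
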