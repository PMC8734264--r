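# Per-sequence structure as probability-weighted interaction sets.
#
# An interaction set is a data.frame with 0-based columns i < j and a
# probability p in (0,1]; it is what the alignment-graph builder consumes,
# whether the structure came from a fixed annotation (p = 1) or from a
# thresholded probability matrix.

validateInteractionSet <- function(x, n = NULL) {
    stopifnot(is.data.frame(x), all(c("i", "j", "p") %in% names(x)))
    if (nrow(x) > 0L) {
        if (any(x$i >= x$j)) stop("interactions must satisfy i < j")
        if (any(x$p <= 0 | x$p > 1)) stop("interaction probabilities must be in (0,1]")
        if (!is.null(n) && (any(x$i < 0) || any(x$j >= n)))
            stop("interaction position out of range")
    }
    invisible(x)
}

emptyInteractionSet <- function() {
    data.frame(i = integer(0), j = integer(0), p = numeric(0))
}

#' Interactions from a fixed pair set
#'
#' Fixed structure annotations (e.g. from dot-bracket) are certain, so every
#' pair carries probability exactly 1.
#'
#' @param ps data.frame of 0-based pairs (`i < j`), e.g. from
#'   [parseDotBracket()].
#' @return Interaction set data.frame with columns `i`, `j`, `p = 1`.
#' @export
pairsToInteractions <- function(ps) {
    validatePairSet(ps)
    if (nrow(ps) == 0L) return(emptyInteractionSet())
    out <- data.frame(i = as.integer(ps$i), j = as.integer(ps$j), p = 1.0)
    out[order(out$i, out$j), , drop = FALSE] -> out
    rownames(out) <- NULL
    out
}

#' Threshold a probability matrix into an interaction set
#'
#' Keeps exactly the upper-triangle entries with probability strictly above
#' `pmin`. Restricting the alignment graph to thermodynamically probable
#' pairs is what keeps the graph (and hence the solver) small.
#'
#' @param x a [BasePairProbMatrix-class].
#' @param pmin probability cutoff in `[0, 1)`; default `1e-3`.
#' @return Interaction set data.frame (`i`, `j`, `p`).
#' @export
thresholdInteractions <- function(x, pmin = 1e-3) {
    stopifnot(pmin >= 0, pmin < 1)
    p <- probMatrix(x)
    idx <- which(upper.tri(p) & p > pmin, arr.ind = TRUE)
    out <- data.frame(i = as.integer(idx[, 1] - 1L),
                      j = as.integer(idx[, 2] - 1L),
                      p = p[idx])
    out <- out[order(out$i, out$j), , drop = FALSE]
    rownames(out) <- NULL
    validateInteractionSet(out, nrow(p))
    out
}

#' Interactions from a dot-bracket annotation, with steric filtering
#'
#' Ingests a dot-bracket string for a concrete sequence: parses (including
#' pseudoknot tiers), drops pairs enclosing fewer than `minLoop` unpaired
#' positions (the minimum hairpin loop; `j - i < minLoop + 1` rejected), and
#' drops pairs involving the wildcard residue `N`. Probability-matrix inputs
#' are deliberately not filtered this way - they are trusted as given.
#'
#' @param text dot-bracket string.
#' @param seq the RNA sequence the annotation belongs to.
#' @param minLoop minimum number of unpaired positions enclosed by a pair
#'   (default 3, i.e. pairs with `j - i < 4` are rejected).
#' @return Interaction set data.frame with `p = 1`.
#' @export
structureFromDotBracket <- function(text, seq, minLoop = 3L) {
    ps <- parseDotBracket(text, nchar(seq))
    if (nrow(ps) > 0L) {
        chars <- strsplit(seq, "")[[1]]
        keep <- (ps$j - ps$i) >= (minLoop + 1L) &
            chars[ps$i + 1L] != "N" & chars[ps$j + 1L] != "N"
        ps <- ps[keep, , drop = FALSE]
    }
    pairsToInteractions(ps)
}

#' Obtain a base-pair probability matrix from an external folding tool
#'
#' Runs a ViennaRNA-compatible folding executable in partition-function mode
#' (`-p`) on one sequence and harvests the `*_dp.ps` dot-plot it writes into
#' the working directory. This step is skipped entirely by the pipeline when
#' structure annotations are supplied.
#'
#' @param seq RNA sequence (character scalar).
#' @param id sequence identifier (used for the FASTA record handed to the
#'   tool).
#' @param executable path to the folding binary, default `"RNAfold"`.
#' @param extraArgs extra command-line arguments.
#' @return A [BasePairProbMatrix-class].
#' @export
foldExternal <- function(seq, id = "seq", executable = "RNAfold",
                         extraArgs = character(0)) {
    exe <- Sys.which(executable)
    if (!nzchar(exe) && file.exists(executable)) exe <- executable
    if (!nzchar(exe) || !file.exists(exe))
        stop("folding executable '", executable, "' not found; either install ",
             "it or supply structure annotations (--structures / --bppm-dir) ",
             "so that folding is skipped")
    wd <- tempfile("fold")
    dir.create(wd)
    on.exit(unlink(wd, recursive = TRUE), add = TRUE)
    fa <- file.path(wd, "input.fa")
    writeLines(c(paste0(">", id), seq), fa)
    old <- setwd(wd)
    on.exit(setwd(old), add = TRUE)
    res <- suppressWarnings(system2(exe, c("-p", "--noPS", extraArgs),
                                    stdin = fa, stdout = TRUE, stderr = TRUE))
    status <- attr(res, "status")
    if (!is.null(status) && status != 0)
        stop("folding tool failed (exit ", status, "): ",
             paste(res, collapse = "\n"))
    dp <- list.files(wd, pattern = "_dp\\.ps$", full.names = TRUE)
    if (length(dp) == 0L)
        dp <- list.files(wd, pattern = "^dot\\.ps$", full.names = TRUE)
    if (length(dp) == 0L)
        stop("folding tool produced no dot-plot (*_dp.ps) in its working directory")
    readBppm(dp[1], dialect = "vienna_dp", n = nchar(seq))
}
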