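# Alignment and structure evaluation: sum-of-pairs score against a reference
# alignment, and the Matthews correlation coefficient over per-sequence
# base-pair confusion counts.

# For a gapped row, the 0-based ungapped position of each alignment column
# (NA at gap columns).
columnToPosition <- function(row) {
    chars <- strsplit(row, "")[[1]]
    pos <- cumsum(chars != "-") - 1L
    pos[chars == "-"] <- NA_integer_
    pos
}

alignedResiduePairs <- function(rows) {
    ids <- names(rows)
    maps <- lapply(rows, columnToPosition)
    out <- list()
    for (a in seq_along(ids)[-length(ids)]) {
        for (b in (a + 1L):length(ids)) {
            both <- !is.na(maps[[a]]) & !is.na(maps[[b]])
            out[[paste(ids[a], ids[b], sep = "|")]] <-
                paste(maps[[a]][both], maps[[b]][both])
        }
    }
    out
}

#' Sum-of-pairs score of a test alignment against a reference
#'
#' The fraction of aligned residue pairs of the reference (over all sequence
#' pairs and columns) that are also aligned in the test alignment; 1 means
#' every reference pair is reproduced, 0 that none is. This is the
#' reference-normalised variant used in BRAliBase-style benchmarking.
#'
#' @param test,ref named character vectors of gapped rows; same ids and same
#'   ungapped sequences required.
#' @return Numeric in `[0, 1]`.
#' @export
spsScore <- function(test, ref) {
    if (is.null(names(test)) || is.null(names(ref)) ||
        !setequal(names(test), names(ref)))
        stop("test and reference alignments must cover the same sequence ids")
    test <- test[names(ref)]
    ug <- function(x) gsub("-", "", x)
    if (!identical(unname(ug(test)), unname(ug(ref))))
        stop("test and reference alignments contain different sequences")
    tp <- alignedResiduePairs(test)
    rp <- alignedResiduePairs(ref)
    total <- sum(lengths(rp))
    if (total == 0L) return(1.0)
    hit <- sum(vapply(names(rp), function(k)
        sum(rp[[k]] %in% tp[[k]]), numeric(1)))
    hit / total
}

#' Per-sequence base-pair confusion counts
#'
#' For each sequence i, `T_i` and `R_i` are the base-pair sets of the test
#' and reference; tp sums the intersections, fp/fn the set differences, and
#' tn the pairs contained in neither set, where the universe per sequence is
#' all C(n_i, 2) unordered position pairs.
#'
#' @param testPairs,refPairs lists of pair-set data.frames (`i < j`,
#'   0-based) indexed by the same sequences.
#' @param lengths integer vector of ungapped sequence lengths.
#' @return List of class `confusionCounts` with `tp`, `fp`, `fn`, `tn`.
#' @export
buildConfusion <- function(testPairs, refPairs, lengths) {
    stopifnot(length(testPairs) == length(refPairs),
              length(lengths) == length(testPairs))
    tp <- fp <- fn <- tn <- 0
    for (s in seq_along(lengths)) {
        n <- lengths[[s]]
        tkey <- with(testPairs[[s]], paste(i, j))
        rkey <- with(refPairs[[s]], paste(i, j))
        pos <- c(testPairs[[s]]$i, testPairs[[s]]$j,
                 refPairs[[s]]$i, refPairs[[s]]$j)
        if (length(pos) && (min(pos) < 0 || max(pos) >= n))
            stop("base pair position out of sequence range")
        tp <- tp + length(intersect(tkey, rkey))
        fp <- fp + length(setdiff(tkey, rkey))
        fn <- fn + length(setdiff(rkey, tkey))
        tn <- tn + choose(n, 2) - length(union(tkey, rkey))
    }
    structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
              class = "confusionCounts")
}

#' Matthews correlation coefficient
#'
#' `MCC = (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, in
#' `[-1, 1]`: 1 is a perfect structure prediction, 0 a random one, -1 total
#' disagreement. When any factor of the denominator is zero the value is 0
#' by convention.
#'
#' @param counts a `confusionCounts` list (see [buildConfusion()]), or four
#'   counts given separately.
#' @param fp,fn,tn individual counts when `counts` is given as `tp`.
#' @return Numeric in `[-1, 1]`.
#' @export
mccScore <- function(counts, fp = NULL, fn = NULL, tn = NULL) {
    if (is.numeric(counts) && !is.null(fp))
        counts <- list(tp = counts, fp = fp, fn = fn, tn = tn)
    with(counts, {
        stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
        den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
        if (den == 0) return(0)
        (tp * tn - fp * fn) / sqrt(den)
    })
}

#' Project a consensus structure onto each row of an alignment
#'
#' Maps consensus base pairs (given in alignment-column coordinates via a
#' dot-bracket string) to the ungapped coordinates of each row, dropping
#' pairs that hit a gap in that row. The consensus folding itself (e.g. by
#' an alignment folding tool) is external to this package.
#'
#' @param rows named character vector of gapped alignment rows.
#' @param consensus dot-bracket string of alignment width.
#' @return Named list of per-sequence pair-set data.frames.
#' @export
projectConsensus <- function(rows, consensus) {
    width <- unique(nchar(rows))
    stopifnot(length(width) == 1L)
    cp <- parseDotBracket(consensus, width)
    lapply(rows, function(row) {
        map <- columnToPosition(row)
        i <- map[cp$i + 1L]
        j <- map[cp$j + 1L]
        keep <- !is.na(i) & !is.na(j)
        ps <- data.frame(i = as.integer(i[keep]), j = as.integer(j[keep]))
        ps[order(ps$i), , drop = FALSE]
    })
}

#' Bootstrap resampling helper for MCC experiments
#'
#' Simple percentile bootstrap over a vector of per-alignment metric values.
#' Provided as a convenience; not calibrated against any published figure.
#'
#' @param values numeric vector of metric values.
#' @param nboot number of bootstrap samples.
#' @param probs quantiles to report.
#' @return Named numeric: median and the requested quantiles of the
#'   bootstrapped medians.
#' @export
bootstrapCI <- function(values, nboot = 1000L, probs = c(0.025, 0.975)) {
    meds <- vapply(seq_len(nboot), function(b)
        stats::median(sample(values, replace = TRUE)), numeric(1))
    c(median = stats::median(values), stats::quantile(meds, probs))
}
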