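# The five-step pipeline behind the command-line interface:
# 1. read sequences and obtain per-sequence structure (annotation, BPPM
#    files, or an external folding tool - folding is skipped when an
#    annotation is supplied);
# 2-4. build the alignment graph and solve every pair by Lagrange iteration;
# 5. write the chosen output format for the downstream MSA tool.

#' Run configuration for the alignment pipeline
#'
#' @param input FASTA file of RNA sequences.
#' @param structures optional dot-bracket annotation file (see
#'   [readDotBracketFile()]).
#' @param bppmDir optional directory of `<id>.bppm` plain 3-column
#'   probability files, one per sequence.
#' @param foldBin external folding executable used when neither
#'   `structures` nor `bppmDir` is given.
#' @param outputFormat `"tcoffee"`, `"mafft"` or `"fasta"`; aligned FASTA
#'   requires exactly two sequences.
#' @param out output file path.
#' @param params an [alignParams()].
#' @param workers worker processes for the all-pairs solve.
#' @param invokeMsa optional downstream MSA command (`"t_coffee"` or
#'   `"mafft-xinsi"`) run on the emitted file; silently skipped unless
#'   requested.
#' @return List of class `runConfig`.
#' @export
runConfig <- function(input, structures = NULL, bppmDir = NULL,
                      foldBin = "RNAfold",
                      outputFormat = c("tcoffee", "mafft", "fasta"),
                      out = "alignment.out", params = alignParams(),
                      workers = 1L, invokeMsa = NULL) {
    outputFormat <- match.arg(outputFormat)
    structure(list(input = input, structures = structures, bppmDir = bppmDir,
                   foldBin = foldBin, outputFormat = outputFormat, out = out,
                   params = params, workers = as.integer(workers),
                   invokeMsa = invokeMsa),
              class = "runConfig")
}

resolveStructures <- function(config, seqs) {
    p <- config$params
    if (!is.null(config$structures)) {
        # annotation supplied: the folding step is omitted
        pairSets <- readDotBracketFile(config$structures, seqs)
        return(mapply(function(ps, q)
            structureFromDotBracket(renderDotBracket(ps, nchar(q)), q),
            pairSets, seqs, SIMPLIFY = FALSE))
    }
    if (!is.null(config$bppmDir)) {
        return(lapply(names(seqs), function(id) {
            f <- file.path(config$bppmDir, paste0(id, ".bppm"))
            if (!file.exists(f)) stop("no BPPM file for sequence ", id,
                                      ": ", f)
            thresholdInteractions(
                readBppm(f, "plain3col", nchar(seqs[[id]])), p$pmin)
        }))
    }
    lapply(names(seqs), function(id)
        thresholdInteractions(foldExternal(seqs[[id]], id, config$foldBin),
                              p$pmin))
}

#' Run the full alignment pipeline
#'
#' Executes the five workflow steps for a [runConfig()]: input, structure
#' acquisition, all-pairs Lagrange solve, and output writing. Convergence of
#' every pair (bounds, iteration count, duality gap) is reported via
#' `message()`.
#'
#' @param config a [runConfig()].
#' @return Invisibly, the list of [StructuralAlignment-class] results.
#' @export
runAlignment <- function(config) {
    stopifnot(inherits(config, "runConfig"))
    seqs <- readRnaFasta(config$input)
    if (length(seqs) < 2L)
        stop("need at least 2 sequences, got ", length(seqs))
    if (config$outputFormat == "fasta" && length(seqs) != 2L)
        stop("aligned FASTA output requires exactly 2 sequences (got ",
             length(seqs), "); use tcoffee or mafft output instead")
    structures <- resolveStructures(config, seqs)
    params <- config$params
    results <- allPairs(seqs, structures, params, config$workers)
    for (r in results)
        message(sprintf(
            "pair %s|%s: zL=%.4f zU=%.4f gap=%.3g iterations=%d%s",
            r@id1, r@id2, r@zLower, r@zUpper, r@zUpper - r@zLower,
            r@iterations, if (r@converged) " converged" else ""))
    if (config$outputFormat == "tcoffee") {
        graphs <- lapply(results, function(r)
            buildAlignmentGraph(gsub("-", "", r@row1), gsub("-", "", r@row2),
                                emptyInteractionSet(), emptyInteractionSet(),
                                params$subst, r@id1, r@id2))
        writeTcoffeeLibrary(results, seqs, config$out, graphs)
    } else if (config$outputFormat == "mafft") {
        writeMafftPairs(results, config$out)
    } else {
        writeAlignedFasta(results, config$out)
    }
    if (!is.null(config$invokeMsa)) {
        exe <- Sys.which(config$invokeMsa)
        if (!nzchar(exe))
            stop("requested MSA tool '", config$invokeMsa, "' not found")
        system2(exe, config$out)
    }
    invisible(results)
}

#' Command-line interface
#'
#' Subcommands: `align` (the pipeline), `simulate` (write a synthetic
#' family fixture directory) and `evaluate` (SPS, and MCC when structures
#' are given, of a test alignment against a reference). Used by the
#' `inst/scripts/knotalign` entry point; requires the `optparse` package.
#'
#' @param args character vector of command-line arguments (subcommand
#'   first), e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return Exit status (0 on success), invisibly.
#' @export
knotAlignCLI <- function(args = commandArgs(trailingOnly = TRUE)) {
    if (length(args) == 0L || args[1] %in% c("-h", "--help")) {
        cat("usage: knotalign <align|simulate|evaluate> [options]\n")
        return(invisible(0L))
    }
    if (!requireNamespace("optparse", quietly = TRUE))
        stop("the command-line interface requires the 'optparse' package")
    sub <- args[1]
    rest <- args[-1]
    switch(sub,
        align = cliAlign(rest),
        simulate = cliSimulate(rest),
        evaluate = cliEvaluate(rest),
        stop("unknown subcommand: ", sub))
    invisible(0L)
}

cliAlign <- function(args) {
    o <- optparse::parse_args(optparse::OptionParser(option_list = list(
        optparse::make_option("--input", type = "character"),
        optparse::make_option("--structures", type = "character",
                              default = NULL),
        optparse::make_option("--bppm-dir", type = "character",
                              default = NULL, dest = "bppmDir"),
        optparse::make_option("--fold-bin", type = "character",
                              default = "RNAfold", dest = "foldBin"),
        optparse::make_option("--pmin", type = "double", default = 1e-3),
        optparse::make_option("--gap-model", type = "character",
                              default = "affine", dest = "gapKind"),
        optparse::make_option("--gap-open", type = "double", default = -6,
                              dest = "gapOpen"),
        optparse::make_option("--gap-extend", type = "double", default = -2,
                              dest = "gapExtend"),
        optparse::make_option("--max-iter", type = "integer", default = 500L,
                              dest = "maxIter"),
        optparse::make_option("--epsilon", type = "double", default = 1e-4),
        optparse::make_option("--lookahead", type = "integer", default = 5L),
        optparse::make_option("--mu0", type = "double", default = 1),
        optparse::make_option("--threads", type = "integer", default = 1L),
        optparse::make_option("--output-format", type = "character",
                              default = "tcoffee", dest = "outputFormat"),
        optparse::make_option("--out", type = "character",
                              default = "alignment.out"),
        optparse::make_option("--invoke-msa", type = "character",
                              default = NULL, dest = "invokeMsa"))),
        args = args)
    if (is.null(o$input)) stop("--input is required")
    params <- alignParams(pmin = o$pmin,
                          gap = gapModel(o$gapKind, o$gapOpen, o$gapExtend),
                          maxIter = o$maxIter, epsilon = o$epsilon,
                          k = o$lookahead, mu0 = o$mu0)
    runAlignment(runConfig(input = o$input, structures = o$structures,
                           bppmDir = o$bppmDir, foldBin = o$foldBin,
                           outputFormat = o$outputFormat, out = o$out,
                           params = params, workers = o$threads,
                           invokeMsa = o$invokeMsa))
}

cliSimulate <- function(args) {
    o <- optparse::parse_args(optparse::OptionParser(option_list = list(
        optparse::make_option("--out-dir", type = "character",
                              default = "family", dest = "outDir"),
        optparse::make_option("--template", type = "character",
                              default = NULL),
        optparse::make_option("--n-sequences", type = "integer", default = 5L,
                              dest = "nSequences"),
        optparse::make_option("--identity", type = "double", default = 0.8),
        optparse::make_option("--compensatory", type = "double",
                              default = 0.9),
        optparse::make_option("--noise", type = "double", default = 0.05),
        optparse::make_option("--seed", type = "integer", default = 42L))),
        args = args)
    spec <- if (is.null(o$template))
        familySpec(nSequences = o$nSequences, targetIdentity = o$identity,
                   compensatoryRate = o$compensatory, bppmNoise = o$noise,
                   seed = o$seed)
    else
        familySpec(template = o$template, nSequences = o$nSequences,
                   targetIdentity = o$identity,
                   compensatoryRate = o$compensatory, bppmNoise = o$noise,
                   seed = o$seed)
    writeFamily(generateFamily(spec), o$outDir)
    message("wrote family fixture to ", o$outDir)
}

cliEvaluate <- function(args) {
    o <- optparse::parse_args(optparse::OptionParser(option_list = list(
        optparse::make_option("--test", type = "character"),
        optparse::make_option("--ref", type = "character"),
        optparse::make_option("--test-structure", type = "character",
                              default = NULL, dest = "testStructure"),
        optparse::make_option("--ref-structure", type = "character",
                              default = NULL, dest = "refStructure"))),
        args = args)
    if (is.null(o$test) || is.null(o$ref))
        stop("--test and --ref are required")
    test <- readAlignedFasta(o$test)
    ref <- readAlignedFasta(o$ref)
    cat(sprintf("SPS %.4f\n", spsScore(test, ref)))
    if (!is.null(o$testStructure) && !is.null(o$refStructure)) {
        tp <- projectConsensus(test, readLines(o$testStructure)[1])
        rp <- projectConsensus(ref, readLines(o$refStructure)[1])
        rp <- rp[names(tp)]
        counts <- buildConfusion(tp, rp, nchar(gsub("-", "", test)))
        cat(sprintf("MCC %.4f\n", mccScore(counts)))
    }
}
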