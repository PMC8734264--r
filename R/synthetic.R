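# Seeded generator of synthetic RNA families with planted structure.
#
# The generator emulates a curated family of homologous structured RNAs: a
# common secondary structure (possibly pseudoknotted), sequence divergence
# dominated by point substitutions with compensatory co-mutation at paired
# sites, and indels confined to unpaired (loop) regions so the planted
# structure is present in every family member. It does not emulate
# thermodynamic folding ensembles, alternative structures, or
# phylogenetic correlation between descendants (all descendants are
# independent draws from the ancestor).

validPairTypes <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' Specification of a synthetic RNA family
#'
#' Defaults describe a compact, well-conserved family: 5 sequences at 80%
#' target identity, 90% compensatory co-mutation at paired sites (structured
#' RNA families preserve pairing far more often than sequence), and mild
#' probability jitter around the planted pairs.
#'
#' @param template dot-bracket template structure (extended brackets allowed
#'   for pseudoknots); the default is an 89-nt three-helix fold of a size
#'   typical for small structured ncRNA families.
#' @param nSequences number of family members, `>= 2`.
#' @param targetIdentity mean pairwise sequence identity aimed for, in
#'   `(0, 1]`.
#' @param compensatoryRate probability that a mutation at a paired site
#'   co-mutates its partner into another valid pair, in `[0, 1]`.
#' @param bppmNoise standard deviation of the jitter applied to the planted
#'   probability of 1.0 (and scale of spurious off-structure entries).
#' @param seed integer seed; a fixed seed makes the family bitwise
#'   reproducible.
#' @return List of class `familySpec`.
#' @export
familySpec <- function(template = paste0(
                           "..((((((...((((....))))...((((......))))...",
                           "))))))..(((((((....)))))))....((((.....))))..."),
                       nSequences = 5L, targetIdentity = 0.8,
                       compensatoryRate = 0.9, bppmNoise = 0.05,
                       seed = 42L) {
    ps <- parseDotBracket(template)            # must parse
    stopifnot(nSequences >= 2L, targetIdentity > 0, targetIdentity <= 1,
              compensatoryRate >= 0, compensatoryRate <= 1, bppmNoise >= 0)
    if (nrow(ps) == 0L && compensatoryRate > 0)
        warning("template has no base pairs; compensatoryRate has no effect")
    structure(list(template = template, nSequences = as.integer(nSequences),
                   targetIdentity = targetIdentity,
                   compensatoryRate = compensatoryRate,
                   bppmNoise = bppmNoise, seed = as.integer(seed)),
              class = "familySpec")
}

# Mutation semantics: a mutated unit is *resampled* uniformly (an unpaired
# site from the 4 bases, a compensatory pair from the 6 valid pair types),
# which makes pairwise identity independent of the ancestor composition.
# For two descendants with per-unit mutation rate m, the probability that a
# site still matches is (1-m)^2 + (2m(1-m) + m^2) * r, where r is the
# probability two resamples agree: r = 1/4 at unpaired sites; at paired
# sites a uniform pair resample keeps/els a given side with probability
# 10/36 (the 5' bases of the 6 pair types are distributed A:1 U:2 G:2 C:1,
# and likewise on the 3' side). The per-descendant rate m is solved from the
# site-type-weighted identity equation for the template at hand.
substRateForIdentity <- function(target, fracPaired, compensatory) {
    if (target >= 1) return(0)
    rPair <- compensatory * 10 / 36 +
        (1 - compensatory) * (1 / 4 + 1) / 2     # 5' resampled, 3' untouched
    f <- function(m) {
        hit <- 2 * m * (1 - m) + m^2
        mu <- (1 - m)^2 + hit / 4
        mp <- (1 - m)^2 + hit * rPair
        (1 - fracPaired) * mu + fracPaired * mp - target
    }
    if (f(0.95) > 0) return(0.95)
    stats::uniroot(f, c(0, 0.95), tol = 1e-10)$root
}

# exactly round(rate * n) draws (stochastic rounding of the fraction)
countForRate <- function(rate, n) {
    x <- rate * n
    k <- floor(x)
    if (stats::runif(1) < x - k) k <- k + 1
    min(n, k)
}

#' Generate a synthetic RNA family
#'
#' Samples an ancestor satisfying the template's complementarity (paired
#' sites drawn from the six valid pair types AU, UA, GC, CG, GU, UG; loops
#' uniform), derives `nSequences` descendants by point substitution with
#' compensatory co-mutation at paired sites, and plants indels only at
#' unpaired template sites so every descendant carries the full structure.
#' Each descendant gets a base-pair probability matrix with probability
#' close to 1 at its planted pairs, mild spurious entries elsewhere.
#'
#' @param spec a [familySpec()].
#' @return List with `sequences` (named character), `pairSets` (per-sequence
#'   planted pairs in ungapped coordinates), `reference` (gapped rows of the
#'   true alignment), `bppms` (list of [BasePairProbMatrix-class]),
#'   `structures` (per-sequence interaction sets from the BPPMs at the
#'   planted pairs), `ancestor` and `template`.
#' @examples
#' fam <- generateFamily(familySpec(nSequences = 3, seed = 7))
#' names(fam$sequences)
#' @export
generateFamily <- function(spec = familySpec()) {
    stopifnot(inherits(spec, "familySpec"))
    withr::with_seed(spec$seed, generateFamilyImpl(spec))
}

generateFamilyImpl <- function(spec) {
    tmpl <- spec$template
    n <- nchar(tmpl)
    pairs <- parseDotBracket(tmpl)
    pairedOf <- rep(NA_integer_, n)                 # 1-based partner map
    if (nrow(pairs) > 0L) {
        pairedOf[pairs$i + 1L] <- pairs$j + 1L
        pairedOf[pairs$j + 1L] <- pairs$i + 1L
    }
    unpairedSites <- which(is.na(pairedOf))

    # ancestor
    anc <- character(n)
    anc[unpairedSites] <- sample(c("A", "C", "G", "U"),
                                 length(unpairedSites), replace = TRUE)
    if (nrow(pairs) > 0L)
        for (r in seq_len(nrow(pairs))) {
            pt <- sample(validPairTypes, 1)
            anc[pairs$i[r] + 1L] <- substr(pt, 1, 1)
            anc[pairs$j[r] + 1L] <- substr(pt, 2, 2)
        }

    fracPaired <- if (n > 0) 2 * nrow(pairs) / n else 0
    m <- substRateForIdentity(spec$targetIdentity, fracPaired,
                              spec$compensatoryRate)
    indelRate <- (1 - spec$targetIdentity) / 4
    ids <- sprintf("seq%02d", seq_len(spec$nSequences))

    # mutation units: each unpaired site and each pair counts once
    units <- c(as.list(unpairedSites),
               if (nrow(pairs) > 0L)
                   lapply(seq_len(nrow(pairs)), function(r)
                       c(pairs$i[r] + 1L, pairs$j[r] + 1L)))

    # descendant rows in template coordinates, plus per-descendant insertions
    rowsTmpl <- matrix("", spec$nSequences, n)
    inserts <- vector("list", spec$nSequences)      # site -> inserted base
    for (d in seq_len(spec$nSequences)) {
        row <- anc
        # resample exactly round(m * #units) units (low-variance scheme)
        k <- countForRate(m, length(units))
        for (u in units[sample(length(units), k)]) {
            if (length(u) == 1L) {
                row[u] <- sample(c("A", "C", "G", "U"), 1)
            } else if (stats::runif(1) < spec$compensatoryRate) {
                pt <- sample(validPairTypes, 1)
                row[u[1]] <- substr(pt, 1, 1)
                row[u[2]] <- substr(pt, 2, 2)
            } else {
                row[u[1]] <- sample(c("A", "C", "G", "U"), 1)
            }
        }
        # deletions at unpaired sites only
        del <- unpairedSites[stats::runif(length(unpairedSites)) < indelRate]
        row[del] <- "-"
        rowsTmpl[d, ] <- row
        # single-base insertions after unpaired sites
        insAt <- unpairedSites[stats::runif(length(unpairedSites)) < indelRate]
        inserts[[d]] <- stats::setNames(
            sample(c("A", "C", "G", "U"), length(insAt), replace = TRUE),
            as.character(insAt))
    }

    # assemble the reference alignment: template columns, with one extra
    # column per insertion event, grouped after its template site
    refRows <- vector("list", spec$nSequences)
    for (d in seq_len(spec$nSequences)) refRows[[d]] <- character(0)
    for (site in seq_len(n)) {
        for (d in seq_len(spec$nSequences))
            refRows[[d]] <- c(refRows[[d]], rowsTmpl[d, site])
        for (d in seq_len(spec$nSequences)) {
            base <- inserts[[d]][as.character(site)]
            if (!is.na(base) && length(base)) {
                for (e in seq_len(spec$nSequences))
                    refRows[[e]] <- c(refRows[[e]],
                                      if (e == d) unname(base) else "-")
            }
        }
    }
    reference <- stats::setNames(
        vapply(refRows, paste, character(1), collapse = ""), ids)
    sequences <- stats::setNames(gsub("-", "", reference), ids)

    # per-sequence planted pairs in ungapped coordinates
    pairSets <- lapply(seq_len(spec$nSequences), function(d) {
        if (nrow(pairs) == 0L)
            return(data.frame(i = integer(0), j = integer(0)))
        tmplPos <- cumsum(rowsTmpl[d, ] != "-")     # per template site
        # offset template positions by insertions occurring at earlier sites
        insSites <- as.integer(names(inserts[[d]]))
        offset <- function(site) sum(insSites < site)
        keep <- rowsTmpl[d, pairs$i + 1L] != "-" & rowsTmpl[d, pairs$j + 1L] != "-"
        pi <- tmplPos[pairs$i[keep] + 1L] +
            vapply(pairs$i[keep] + 1L, offset, numeric(1)) - 1L
        pj <- tmplPos[pairs$j[keep] + 1L] +
            vapply(pairs$j[keep] + 1L, offset, numeric(1)) - 1L
        ps <- data.frame(i = as.integer(pi), j = as.integer(pj))
        ps[order(ps$i), , drop = FALSE]
    })
    names(pairSets) <- ids

    # per-sequence probability matrices: ~1 at planted pairs, sparse small
    # spurious entries confined to rows without a planted pair
    bppms <- lapply(seq_len(spec$nSequences), function(d) {
        nd <- nchar(sequences[[d]])
        mat <- matrix(0, nd, nd)
        ps <- pairSets[[d]]
        if (nrow(ps) > 0L) {
            pvals <- pmin(1, pmax(0.5, 1 - abs(stats::rnorm(nrow(ps), 0,
                                                            spec$bppmNoise))))
            mat[cbind(ps$i + 1L, ps$j + 1L)] <- pvals
            mat[cbind(ps$j + 1L, ps$i + 1L)] <- pvals
        }
        pairedRows <- c(ps$i, ps$j) + 1L
        free <- setdiff(seq_len(nd), pairedRows)
        nNoise <- min(length(free) %/% 2L, max(0L, nd %/% 5L))
        if (nNoise > 0L && spec$bppmNoise > 0) {
            picks <- matrix(sample(free, 2L * nNoise), ncol = 2L)
            for (r in seq_len(nNoise)) {
                a <- min(picks[r, ]); b <- max(picks[r, ])
                val <- min(abs(stats::rnorm(1, 0, spec$bppmNoise)), 0.2)
                if (val > 0 &&
                    sum(mat[a, ]) + val <= 0.95 && sum(mat[b, ]) + val <= 0.95) {
                    mat[a, b] <- mat[b, a] <- val
                }
            }
        }
        bppm(mat)
    })
    names(bppms) <- ids

    structures <- lapply(bppms, thresholdInteractions, pmin = 1e-3)

    list(sequences = sequences, pairSets = pairSets, reference = reference,
         bppms = bppms, structures = structures,
         ancestor = paste(anc, collapse = ""), template = tmpl)
}

#' Write a synthetic family as a self-contained fixture directory
#'
#' Emits FASTA sequences, per-sequence dot-bracket annotations, plain
#' 3-column probability matrices and the aligned FASTA reference.
#'
#' @param fam result of [generateFamily()].
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
writeFamily <- function(fam, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeFasta(fam$sequences, file.path(dir, "sequences.fa"))
    db <- vapply(names(fam$sequences), function(id)
        renderDotBracket(fam$pairSets[[id]], nchar(fam$sequences[[id]])),
        character(1))
    writeLines(unlist(lapply(names(fam$sequences), function(id)
        c(paste0(">", id), fam$sequences[[id]], db[[id]]))),
        file.path(dir, "structures.db"))
    for (id in names(fam$bppms))
        writeBppm(fam$bppms[[id]], file.path(dir, paste0(id, ".bppm")))
    writeFasta(fam$reference, file.path(dir, "reference.afa"))
    invisible(dir)
}
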