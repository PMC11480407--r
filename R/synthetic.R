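#' @include AllClasses.R decoding.R essentiality.R
NULL

# Run expr under a fixed seed, leaving the caller's RNG state untouched.
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else suppressWarnings(rm(".Random.seed", envir = globalenv()))
    })
    set.seed(seed)
    force(expr)
}

#' Simulate a complete tRNA registry with planted essential TUs
#'
#' Generates a random-but-viable registry: every sense codon gets at
#' least one elongator decoder (greedy coverage: walk the codons in fixed
#' order and, for each still-uncovered codon, add a gene whose anticodon
#' is its strict Watson-Crick complement), redundant copies are then added
#' per-anticodon with the requested copy-number distribution, plus
#' `nInitiators` initiator fMet genes. Genes are partitioned into
#' `nTus` transcription units uniformly at random; for each planted
#' essential TU, one codon is chosen and *all* of its decoders are placed
#' inside that TU, so deleting the TU provably orphans the codon.
#'
#' The returned ground truth is recomputed from the finished registry by
#' direct enumeration (a TU is truly essential iff some codon's entire
#' decoder set, or the entire initiator set, lies inside it), so it also
#' captures TUs that become essential by chance placement of sole
#' decoders. Identical seeds give bit-identical output.
#'
#' @param nTus Number of transcription units (>= 2).
#' @param plantedEssentialTus Number of TUs to make essential by
#'   construction (0 <= planted <= nTus - 1).
#' @param copiesPerAnticodon Probability weights for 1, 2, ... gene
#'   copies per seeded anticodon.
#' @param nInitiators Number of initiator fMet genes.
#' @param seed Integer seed; the caller's RNG state is preserved.
#' @param ruleset A [WobbleRuleSet-class] (bare-base rules are used since
#'   simulated genes carry no modifications).
#' @return List with elements `registry` ([TRNARegistry-class]),
#'   `essentialTus` (ground-truth essential TU ids) and `plantedTus`.
#' @examples
#' sim <- simulateRegistry(nTus = 6, plantedEssentialTus = 2, seed = 1)
#' sim$plantedTus
#' @export
simulateRegistry <- function(nTus = 8, plantedEssentialTus = 0,
                             copiesPerAnticodon = c(0.5, 0.3, 0.2),
                             nInitiators = 2, seed = 1,
                             ruleset = defaultWobbleRules()) {
    stopifnot(nTus >= 2, nInitiators >= 1,
              plantedEssentialTus >= 0)
    if (plantedEssentialTus > nTus - 1L)
        stop("infeasible: planted TUs must leave at least one free TU",
             call. = FALSE)
    .withSeed(seed, {
        sense <- senseCodons()
        anticodons <- character()
        covered <- character()
        for (cod in sense) {
            if (cod %in% covered) next
            ac <- cognateCodon(cod)  # revcomp is an involution
            anticodons <- c(anticodons, ac)
            covered <- union(covered, .decodedCodons(ac, "", ruleset))
        }
        copies <- sample(seq_along(copiesPerAnticodon),
                         length(anticodons), replace = TRUE,
                         prob = copiesPerAnticodon)
        ac <- rep(anticodons, copies)
        aa <- .codonAA(vapply(ac, cognateCodon, character(1)))
        genes <- data.frame(
            gene = sprintf("syn%03d", seq_along(ac)),
            amino_acid = unname(aa), anticodon = unname(ac),
            modification = "", class = "elongator",
            stringsAsFactors = FALSE)
        init <- data.frame(
            gene = sprintf("ini%02d", seq_len(nInitiators)),
            amino_acid = "Met", anticodon = "CAU", modification = "",
            class = "initiator", stringsAsFactors = FALSE)
        genes <- rbind(genes, init)
        n <- nrow(genes)

        tuIds <- sprintf("TU%02d", seq_len(nTus))
        assign <- sample(nTus, n, replace = TRUE)

        # decoder sets (elongators only) for planting and ground truth
        elong <- genes$class == "elongator"
        decSets <- lapply(which(elong), function(i)
            intersect(.decodedCodons(genes$anticodon[i],
                                     genes$modification[i], ruleset),
                      sense))
        decoders <- lapply(sense, function(cod)
            which(elong)[vapply(decSets, function(s) cod %in% s,
                                logical(1))])
        names(decoders) <- sense

        planted <- character()
        claimed <- integer()
        if (plantedEssentialTus > 0) {
            for (cod in sample(sense)) {
                if (length(planted) == plantedEssentialTus) break
                d <- decoders[[cod]]
                if (length(d) == 0L || any(d %in% claimed)) next
                tu <- length(planted) + 1L
                assign[d] <- tu
                claimed <- c(claimed, d)
                planted <- c(planted, tuIds[tu])
            }
            if (length(planted) < plantedEssentialTus)
                stop("infeasible: could not find ",
                     plantedEssentialTus,
                     " codons with disjoint decoder sets", call. = FALSE)
        }
        # keep every TU nonempty without touching claimed genes
        free <- setdiff(seq_len(n), claimed)
        for (tu in seq_len(nTus)) {
            if (any(assign == tu)) next
            movable <- free[assign[free] %in%
                                which(tabulate(assign, nTus) > 1L)]
            if (length(movable) == 0L)
                stop("infeasible: not enough genes to fill ", nTus,
                     " TUs", call. = FALSE)
            assign[movable[1]] <- tu
        }

        genes$tu_id <- tuIds[assign]
        tus <- data.frame(tu_id = tuIds, display_name = tuIds,
                          non_trna = FALSE, stringsAsFactors = FALSE)
        reg <- new("TRNARegistry", genes = genes, tus = tus,
                   provenance = paste("synthetic registry, seed", seed))

        # ground-truth recount by direct enumeration over the finished TUs
        truth <- vapply(seq_len(nTus), function(tu) {
            members <- which(assign == tu)
            codonHit <- any(vapply(decoders, function(d)
                length(d) > 0L && all(d %in% members), logical(1)))
            initHit <- all(which(!elong) %in% members)
            codonHit || initHit
        }, logical(1))
        list(registry = reg, essentialTus = tuIds[truth],
             plantedTus = planted)
    })
}

#' Simulate a differential-expression table with known true effects
#'
#' Emulates the statistical structure of a per-gene DGE table: a fraction
#' `fracDE` of genes carry a true effect with |log2FC| drawn uniformly on
#' \[`lfcCut`, `lfcCut + effectWidth`\] (random sign) plus measurement
#' noise, and p-values drawn from a Beta(`betaShape1`, 1) distribution
#' (stochastically smaller than uniform); null genes have
#' Normal(0, `nullSd`) log2FC and Uniform(0,1) p-values. FDR values are
#' Benjamini-Hochberg adjusted across all genes. Identical seeds give
#' bit-identical tables.
#'
#' @param nGenes Number of genes.
#' @param fracDE Fraction of genes with a true effect, in \[0,1\].
#' @param lfcCut Lower bound of true effect sizes (matches the calling
#'   threshold so planted effects are recoverable).
#' @param effectWidth Width of the uniform effect-size distribution.
#' @param nullSd Standard deviation of null log2FC noise.
#' @param deNoiseSd Measurement noise added to true effects.
#' @param betaShape1 First shape of the true-effect p-value Beta.
#' @param seed Integer seed.
#' @return List with `records` (data.frame `gene_id`, `log2fc`, `pvalue`,
#'   `fdr`, `label`) and `trueDEGs` (character vector).
#' @examples
#' sim <- simulateDGE(nGenes = 200, fracDE = 0.1, seed = 7)
#' length(sim$trueDEGs)  # 20
#' @export
simulateDGE <- function(nGenes = 2000, fracDE = 0.1, lfcCut = 1.5,
                        effectWidth = 2, nullSd = 0.5, deNoiseSd = 0.1,
                        betaShape1 = 0.05, seed = 1) {
    stopifnot(nGenes >= 1, fracDE >= 0, fracDE <= 1, lfcCut > 0)
    .withSeed(seed, {
        ids <- sprintf("gene%05d", seq_len(nGenes))
        nDE <- round(fracDE * nGenes)
        de <- sort(sample(nGenes, nDE))
        lfc <- stats::rnorm(nGenes, 0, nullSd)
        p <- stats::runif(nGenes)
        if (nDE > 0) {
            effect <- stats::runif(nDE, lfcCut, lfcCut + effectWidth) *
                sample(c(-1, 1), nDE, replace = TRUE)
            lfc[de] <- effect + stats::rnorm(nDE, 0, deNoiseSd)
            p[de] <- stats::rbeta(nDE, betaShape1, 1)
        }
        records <- data.frame(gene_id = ids, log2fc = lfc, pvalue = p,
                              fdr = bhAdjust(p), label = "",
                              stringsAsFactors = FALSE)
        list(records = records, trueDEGs = ids[de])
    })
}

#' Write a simulated DGE table in the loader dialect
#'
#' @param sim Result of [simulateDGE()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
writeDGETable <- function(sim, path) {
    records <- if (is.data.frame(sim)) sim else sim$records
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
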