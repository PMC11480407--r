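#' @include AllClasses.R
NULL

# Strict Watson-Crick partners, RNA alphabet.
.WC <- c(A = "U", C = "G", G = "C", U = "A")

# Genetic-code tables derived once from the standard bacterial code.
.codeEnv <- new.env(parent = emptyenv())

.geneticCode <- function() {
    if (is.null(.codeEnv$code)) {
        code <- Biostrings::RNA_GENETIC_CODE
        .codeEnv$code <- code
        .codeEnv$sense <- sort(names(code)[code != "*"])
        .codeEnv$stop <- sort(names(code)[code == "*"])
        aa3 <- Biostrings::AMINO_ACID_CODE
        .codeEnv$aa3 <- aa3
    }
    .codeEnv$code
}

#' The standard genetic code over the RNA alphabet
#'
#' `geneticCode()` returns the 64-codon table (codon -> one-letter amino
#' acid, `*` for stop); `senseCodons()` the 61 sense codons and
#' `stopCodons()` the 3 stop codons, each sorted.
#'
#' @return Named character vector (`geneticCode`) or character vector of
#'   codons.
#' @examples
#' length(senseCodons())  # 61
#' stopCodons()
#' @export
geneticCode <- function() .geneticCode()

#' @rdname geneticCode
#' @export
senseCodons <- function() { .geneticCode(); .codeEnv$sense }

#' @rdname geneticCode
#' @export
stopCodons <- function() { .geneticCode(); .codeEnv$stop }

# Three-letter amino acid of a sense codon ("Ala", ...); "Stp" for stops.
.codonAA <- function(codon) {
    code <- .geneticCode()
    one <- code[codon]
    ifelse(one == "*", "Stp", unname(.codeEnv$aa3[one]))
}

.checkTriplet <- function(x, what) {
    if (!is.character(x) || length(x) != 1L || is.na(x))
        stop(what, " must be a single string", call. = FALSE)
    if (nchar(x) != 3L)
        stop(what, " '", x, "' must have length 3", call. = FALSE)
    b <- strsplit(x, "")[[1]]
    if (!all(b %in% .RNA_BASES))
        stop(what, " '", x, "' contains bases outside A/C/G/U ",
             "(RNA alphabet, 5'->3')", call. = FALSE)
    invisible(x)
}

#' Cognate codon of an anticodon
#'
#' The codon read by strict Watson-Crick pairing of all three anticodon
#' positions: the anticodon (tRNA positions 34-36, written 5'->3') pairs
#' antiparallel with the codon, so anticodon position 36 pairs with codon
#' position 1. Computed as the reverse complement. For example the GGC
#' anticodon of the alaWX alanine tRNAs has cognate codon GCC, and the GAC
#' anticodon of valVW has cognate GUC.
#'
#' @param anticodon Single anticodon string over `A/C/G/U`, 5'->3'.
#' @return The cognate codon, 5'->3'.
#' @examples
#' cognateCodon("GGC")  # "GCC"
#' cognateCodon("GAC")  # "GUC"
#' @export
cognateCodon <- function(anticodon) {
    .checkTriplet(anticodon, "anticodon")
    as.character(Biostrings::reverseComplement(Biostrings::RNAString(anticodon)))
}

# Effective wobble key of a gene row: modification label when present,
# otherwise the bare position-34 base (first base of the 5'->3' anticodon).
.wobbleKey <- function(anticodon, modification) {
    mod <- as.character(modification)
    bare <- is.na(mod) | mod == ""
    ifelse(bare, substr(anticodon, 1L, 1L), mod)
}

.ruleThirds <- function(key, ruleset) {
    unknown <- setdiff(unique(key), names(ruleset@rules))
    if (length(unknown))
        stop("unknown wobble key(s) in rule set '", ruleset@version, "': ",
             paste(unknown, collapse = ", "), call. = FALSE)
    ruleset@rules[key]
}

# All codons (sense or not) a single anticodon+modification can read.
.decodedCodons <- function(anticodon, modification, ruleset) {
    key <- .wobbleKey(anticodon, modification)
    thirds <- .ruleThirds(key, ruleset)[[1]]
    prefix <- paste0(.WC[substr(anticodon, 3L, 3L)],
                     .WC[substr(anticodon, 2L, 2L)])
    paste0(prefix, thirds)
}

.asGeneRow <- function(gene) {
    if (is(gene, "TRNARegistry"))
        stop("'gene' must be a single gene (a row of genes(registry)), ",
             "not a registry", call. = FALSE)
    if (is.data.frame(gene)) {
        if (nrow(gene) != 1L)
            stop("'gene' must be exactly one gene row", call. = FALSE)
        gene <- as.list(gene)
    }
    if (is.null(gene$anticodon))
        stop("'gene' needs an 'anticodon' field", call. = FALSE)
    if (is.null(gene$modification)) gene$modification <- ""
    gene
}

#' Can a tRNA gene decode a codon?
#'
#' TRUE iff codon positions 1 and 2 are strict Watson-Crick complements of
#' anticodon positions 36 and 35, and the codon third-position base is
#' readable by the gene's effective wobble key (its position-34
#' modification label when set, else the bare position-34 base). The
#' functional class of the gene plays no role here.
#'
#' @param gene A single gene: a one-row data.frame or list with fields
#'   `anticodon` and optionally `modification`.
#' @param codon Single codon string over `A/C/G/U`, 5'->3'.
#' @param ruleset A [WobbleRuleSet-class]; defaults to
#'   [defaultWobbleRules()].
#' @return Logical scalar.
#' @examples
#' rules <- defaultWobbleRules()
#' decodes(list(anticodon = "GGC"), "GCU", rules)                    # TRUE
#' decodes(list(anticodon = "UGC", modification = "cmo5U"), "GCC", rules) # TRUE
#' decodes(list(anticodon = "GGC"), "GCA", rules)                    # FALSE
#' @export
decodes <- function(gene, codon, ruleset = defaultWobbleRules()) {
    .checkTriplet(codon, "codon")
    gene <- .asGeneRow(gene)
    .checkTriplet(gene$anticodon, "anticodon")
    codon %in% .decodedCodons(gene$anticodon, gene$modification, ruleset)
}

.genesTable <- function(genes) {
    if (is(genes, "TRNARegistry")) genes <- genes@genes
    if (!is.data.frame(genes) || is.null(genes$gene) ||
        is.null(genes$anticodon))
        stop("'genes' must be a TRNARegistry or a data.frame with at least ",
             "'gene' and 'anticodon' columns", call. = FALSE)
    if (is.null(genes$modification))
        genes$modification <- rep("", nrow(genes))
    genes
}

#' Codon-to-decoder table
#'
#' For every one of the 61 sense codons, the (name-sorted) list of genes
#' that can decode it under the rule set. Stop codons never appear as
#' keys. Adding genes can only grow the per-codon decoder lists.
#'
#' @param genes A [TRNARegistry-class] or a gene data.frame (columns
#'   `gene`, `anticodon`, optional `modification`).
#' @param ruleset A [WobbleRuleSet-class].
#' @return Named list, one element per sense codon (possibly empty
#'   character vector).
#' @examples
#' tab <- decodingTable(loadRegistry("mg1655"))
#' tab[["GCC"]]  # decoders of the frequent alanine codon
#' @export
decodingTable <- function(genes, ruleset = defaultWobbleRules()) {
    g <- .genesTable(genes)
    sense <- senseCodons()
    tab <- stats::setNames(vector("list", length(sense)), sense)
    for (cod in sense) tab[[cod]] <- character()
    if (nrow(g)) {
        key <- .wobbleKey(g$anticodon, g$modification)
        thirds <- .ruleThirds(key, ruleset)
        for (i in seq_len(nrow(g))) {
            prefix <- paste0(.WC[substr(g$anticodon[i], 3L, 3L)],
                             .WC[substr(g$anticodon[i], 2L, 2L)])
            for (cod in intersect(paste0(prefix, thirds[[i]]), sense))
                tab[[cod]] <- c(tab[[cod]], g$gene[i])
        }
        tab <- lapply(tab, function(x) sort(unique(x)))
    }
    tab
}
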