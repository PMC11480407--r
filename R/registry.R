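#' @include AllClasses.R decoding.R
NULL

.REGISTRY_TSV_COLS <- c("gene", "amino_acid", "anticodon", "modification",
                        "class", "tu_id", "tu_display_name", "tu_non_trna")

# Elongator anticodon/amino-acid consistency under the genetic code.
# Lysidine (k2C) recodes the CAU anticodon from Met to Ile, so k2C-CAU-Ile
# is treated as consistent.
.checkGeneCodeConsistency <- function(g) {
    el <- g$class == "elongator"
    cod <- vapply(g$anticodon, cognateCodon, character(1))
    aa <- .codonAA(cod)
    ok <- !el | aa == g$amino_acid |
        (g$modification == "k2C" & g$anticodon == "CAU" &
             g$amino_acid == "Ile")
    if (any(!ok))
        warning("anticodon/amino-acid mismatch under the genetic code for ",
                "gene(s): ", paste(g$gene[!ok], collapse = ", "),
                " (tolerated as annotation quirk)", call. = FALSE)
    invisible(ok)
}

#' Load a tRNA gene / transcription-unit registry
#'
#' Reads the tab-separated registry dialect (UTF-8, header row, columns
#' `gene`, `amino_acid`, `anticodon`, `modification`, `class`, `tu_id`,
#' `tu_display_name`, `tu_non_trna`; anticodons 5'->3' in the RNA
#' alphabet). `source = "mg1655"` loads the packaged E. coli K-12 MG1655
#' fixture: 86 tRNA genes in 43 transcription units, compiled from
#' canonical annotation (EcoCyc/GtRNAdb content transcribed at build
#' time). DNA-alphabet anticodons (T instead of U) are converted on input
#' and the conversion is recorded in the provenance notes.
#'
#' All registry invariants are checked on load; violations are reported
#' with the offending rows.
#'
#' @param source Path to a registry TSV, or the builtin identifier
#'   `"mg1655"`.
#' @return A [TRNARegistry-class].
#' @examples
#' reg <- loadRegistry("mg1655")
#' nGenes(reg)  # 86
#' nTUs(reg)    # 43
#' @export
loadRegistry <- function(source = "mg1655") {
    prov <- character()
    if (identical(source, "mg1655")) {
        source <- system.file("extdata", "mg1655_trna_registry.tsv",
                              package = "tRNAessentials", mustWork = TRUE)
        prov <- paste("builtin MG1655 fixture: TU composition and anticodons",
                      "from canonical E. coli K-12 MG1655 annotation",
                      "(EcoCyc/GtRNAdb), canonical anticodons used",
                      "throughout")
    }
    if (!file.exists(source))
        stop("registry source not found: ", source, call. = FALSE)
    g <- utils::read.delim(source, colClasses = "character",
                           na.strings = NULL, check.names = TRUE)
    miss <- setdiff(.REGISTRY_TSV_COLS, names(g))
    if (length(miss))
        stop("registry TSV ", source, " lacks column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    if (nrow(g) == 0L)
        stop("registry TSV is empty: ", source, call. = FALSE)
    if (any(grepl("T", g$anticodon, fixed = TRUE))) {
        g$anticodon <- chartr("T", "U", g$anticodon)
        prov <- c(prov, "anticodons converted from DNA to RNA alphabet (T->U)")
    }
    bad <- which(!.validAnticodon(g$anticodon))
    if (length(bad))
        stop("bad anticodon in registry row(s) ",
             paste(bad, collapse = ", "), ": ",
             paste(unique(g$anticodon[bad]), collapse = ", "), call. = FALSE)
    dup <- which(duplicated(g$gene))
    if (length(dup))
        stop("duplicate gene name in registry row(s) ",
             paste(dup, collapse = ", "), ": ",
             paste(unique(g$gene[dup]), collapse = ", "), call. = FALSE)
    tu <- unique(g[, c("tu_id", "tu_display_name", "tu_non_trna")])
    if (anyDuplicated(tu$tu_id))
        stop("TU id(s) with inconsistent display metadata: ",
             paste(unique(tu$tu_id[duplicated(tu$tu_id)]), collapse = ", "),
             call. = FALSE)
    tus <- data.frame(tu_id = tu$tu_id, display_name = tu$tu_display_name,
                      non_trna = tu$tu_non_trna == "1",
                      stringsAsFactors = FALSE)
    genes <- g[, .GENE_COLS]
    rownames(genes) <- NULL
    reg <- new("TRNARegistry", genes = genes, tus = tus,
               provenance = c(paste("loaded from", source), prov))
    .checkGeneCodeConsistency(genes)
    reg
}

#' Write a registry back to the TSV dialect
#'
#' Inverse of [loadRegistry()]: `loadRegistry(writeRegistry(reg, f))`
#' reproduces `reg` (up to provenance notes).
#'
#' @param registry A [TRNARegistry-class].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
writeRegistry <- function(registry, path) {
    stopifnot(is(registry, "TRNARegistry"))
    g <- registry@genes
    tu <- registry@tus
    i <- match(g$tu_id, tu$tu_id)
    out <- cbind(g, tu_display_name = tu$display_name[i],
                 tu_non_trna = as.integer(tu$non_trna[i]))
    utils::write.table(out[, .REGISTRY_TSV_COLS], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Export a registry as JSON
#'
#' Nested JSON (one object per TU with its gene list) for reports.
#'
#' @param registry A [TRNARegistry-class].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
registryToJSON <- function(registry, path = NULL) {
    stopifnot(is(registry, "TRNARegistry"))
    g <- registry@genes
    tu <- registry@tus
    obj <- list(
        n_genes = nrow(g), n_tus = nrow(tu),
        provenance = registry@provenance,
        tus = lapply(seq_len(nrow(tu)), function(i) {
            gi <- g[g$tu_id == tu$tu_id[i], ]
            list(tu_id = tu$tu_id[i], display_name = tu$display_name[i],
                 contains_non_trna_elements = tu$non_trna[i],
                 genes = lapply(seq_len(nrow(gi)), function(j)
                     as.list(gi[j, .GENE_COLS])))
        }))
    js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
    if (is.null(path)) return(js)
    writeLines(js, path)
    invisible(js)
}

#' Genome-wide copy number of an isoacceptor
#'
#' Number of gene copies in the registry matching an amino acid, anticodon
#' and functional class. In MG1655 e.g. six elongator Lys-UUU copies exist
#' (five of them in the lysT-valT-lysW-valZ-lysYZQ operon) and two
#' lysidine-modified Ile-CAU copies (ileX, ileY).
#'
#' @param registry A [TRNARegistry-class].
#' @param aminoAcid Three-letter amino-acid label (e.g. `"Lys"`).
#' @param anticodon Anticodon 5'->3'.
#' @param class Functional class; default `"elongator"`.
#' @return Integer count (0 for an absent combination).
#' @examples
#' copyNumber(loadRegistry("mg1655"), "Lys", "UUU")  # 6
#' @export
copyNumber <- function(registry, aminoAcid, anticodon,
                       class = "elongator") {
    stopifnot(is(registry, "TRNARegistry"))
    g <- registry@genes
    sum(g$amino_acid == aminoAcid & g$anticodon == anticodon &
            g$class == class)
}

#' In-TU vs genome-wide copies of an isoacceptor
#'
#' How many of the genome-wide gene copies carrying a given amino acid and
#' anticodon lie inside one transcription unit. Reproduces the
#' copy-number fractions reported for the deletion screen, e.g. 5/6
#' Lys-UUU copies inside lysT-valT-lysW-valZ-lysYZQ and 1/2 Ile-CAU
#' copies inside ileX.
#'
#' @inheritParams copyNumber
#' @param tuId TU identifier (must exist in the registry).
#' @return Named integer vector `c(in_tu =, genome =)` with
#'   `in_tu <= genome`.
#' @examples
#' reg <- loadRegistry("mg1655")
#' tuCopyFraction(reg, "lysT-valT-lysW-valZ-lysYZQ", "Lys", "UUU")  # 5, 6
#' tuCopyFraction(reg, "ileX", "Ile", "CAU")                       # 1, 2
#' @export
tuCopyFraction <- function(registry, tuId, aminoAcid, anticodon) {
    stopifnot(is(registry, "TRNARegistry"))
    if (!tuId %in% registry@tus$tu_id)
        stop("unknown tu_id: ", tuId, call. = FALSE)
    g <- registry@genes
    hit <- g$amino_acid == aminoAcid & g$anticodon == anticodon
    c(in_tu = sum(hit & g$tu_id == tuId), genome = sum(hit))
}
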