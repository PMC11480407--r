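#' @include AllClasses.R decoding.R registry.R
NULL

# The fixed demand set: all 61 sense codons must be decodable by at least
# one elongator tRNA, and at least one initiator (fMet) gene must remain.
# Selenocysteine tRNA (UGA recoding) creates no demand and covers none.

.checkTuIds <- function(registry, tuIds) {
    unknown <- setdiff(tuIds, registry@tus$tu_id)
    if (length(unknown))
        stop("unknown tu_id(s): ", paste(unknown, collapse = ", "),
             call. = FALSE)
    invisible(tuIds)
}

# Orphaned demands after removing a set of TUs: sense codons with no
# remaining elongator decoder, plus "initiation" when no initiator remains.
.orphanedDemands <- function(registry, deletedTuIds, ruleset) {
    g <- registry@genes
    keep <- !(g$tu_id %in% deletedTuIds)
    elong <- g[keep & g$class == "elongator", , drop = FALSE]
    tab <- decodingTable(elong, ruleset)
    orph <- sort(names(tab)[lengths(tab) == 0L])
    if (!any(keep & g$class == "initiator"))
        orph <- c(orph, "initiation")
    orph
}

#' Orphaned decoding demands after deleting a set of TUs
#'
#' Generalizes the single-TU screen to simultaneous deletions: which of
#' the 62 decoding demands (61 sense codons plus translation initiation)
#' are no longer served by the genes outside the deleted TUs. An empty
#' deletion leaves no orphan in a viable registry.
#'
#' @param registry A [TRNARegistry-class].
#' @param deletedTuIds Character vector of TU ids (may be empty).
#' @param ruleset A [WobbleRuleSet-class].
#' @return Sorted character vector of orphaned demands (codons, possibly
#'   `"initiation"`).
#' @examples
#' reg <- loadRegistry("mg1655")
#' coverageGap(reg, character())  # empty
#' coverageGap(reg, "argU")       # "AGA": argU is the sole AGA decoder
#' @export
coverageGap <- function(registry, deletedTuIds,
                        ruleset = defaultWobbleRules()) {
    stopifnot(is(registry, "TRNARegistry"))
    .checkTuIds(registry, deletedTuIds)
    .orphanedDemands(registry, deletedTuIds, ruleset)
}

#' Classify one transcription unit as essential or not
#'
#' In-silico deletion: remove the TU's genes and ask whether every
#' decoding demand -- each of the 61 sense codons, served by elongator
#' tRNAs under the wobble rules, and translation initiation, served by
#' initiator fMet genes -- is still met by the rest of the genome. The TU
#' is `predicted-essential` iff at least one demand is orphaned. The
#' essential elements are the genes inside the TU that serve an orphaned
#' demand; copy fractions report, for each isoacceptor present in the TU,
#' how many of its genome-wide copies the TU holds.
#'
#' The criterion is pure demand coverage: it asks whether any decoder
#' remains, not whether the remaining copy number or expression level is
#' sufficient. Deletions whose lethality stems from dosage (a single
#' remaining gene copy that cannot sustain growth) are therefore
#' predicted non-essential by design.
#'
#' @param registry A [TRNARegistry-class].
#' @param tuId TU identifier.
#' @param ruleset A [WobbleRuleSet-class].
#' @return A [TUClassification-class].
#' @examples
#' reg <- loadRegistry("mg1655")
#' classifyTU(reg, "serT")                  # essential: sole UCA decoder
#' classifyTU(reg, "argX-hisR-leuT-proM")   # essential via hisR and proM
#' classifyTU(reg, "alaWX")                 # non-essential: UGC copies wobble
#' @export
classifyTU <- function(registry, tuId, ruleset = defaultWobbleRules()) {
    stopifnot(is(registry, "TRNARegistry"))
    .checkTuIds(registry, tuId)
    orph <- .orphanedDemands(registry, tuId, ruleset)
    g <- registry@genes
    inTU <- g[g$tu_id == tuId, , drop = FALSE]

    orphCodons <- setdiff(orph, "initiation")
    elems <- logical(nrow(inTU))
    for (i in seq_len(nrow(inTU))) {
        if (inTU$class[i] == "elongator" && length(orphCodons))
            elems[i] <- any(.decodedCodons(inTU$anticodon[i],
                                           inTU$modification[i],
                                           ruleset) %in% orphCodons)
        if (inTU$class[i] == "initiator" && "initiation" %in% orph)
            elems[i] <- TRUE
    }
    ee <- inTU[elems, c("gene", "anticodon")]
    ee <- ee[order(ee$gene), , drop = FALSE]
    rownames(ee) <- NULL

    iso <- unique(inTU[, c("amino_acid", "anticodon")])
    cf <- do.call(rbind, lapply(seq_len(nrow(iso)), function(i) {
        ct <- tuCopyFraction(registry, tuId, iso$amino_acid[i],
                             iso$anticodon[i])
        data.frame(amino_acid = iso$amino_acid[i],
                   anticodon = iso$anticodon[i],
                   in_tu = unname(ct["in_tu"]),
                   genome = unname(ct["genome"]),
                   stringsAsFactors = FALSE)
    }))
    cf <- cf[order(cf$amino_acid, cf$anticodon), , drop = FALSE]
    rownames(cf) <- NULL

    new("TUClassification", tuId = tuId,
        status = if (length(orph)) "predicted-essential"
                 else "predicted-non-essential",
        orphanedDemands = orph, essentialElements = ee,
        copyFractions = cf)
}

#' Screen every transcription unit of a registry
#'
#' Runs [classifyTU()] for each TU, in registry order, and summarises the
#' predicted-essential / predicted-non-essential counts. The screen is
#' fully deterministic.
#'
#' @param registry A [TRNARegistry-class].
#' @param ruleset A [WobbleRuleSet-class].
#' @return A [TUScreen-class].
#' @examples
#' scr <- screenTUs(loadRegistry("mg1655"))
#' screenSummary(scr)$nPredictedEssential  # 8
#' @export
screenTUs <- function(registry, ruleset = defaultWobbleRules()) {
    stopifnot(is(registry, "TRNARegistry"))
    cls <- lapply(registry@tus$tu_id, classifyTU, registry = registry,
                  ruleset = ruleset)
    ness <- sum(vapply(cls, function(x)
        x@status == "predicted-essential", logical(1)))
    new("TUScreen", classifications = cls,
        summary = list(nTUs = length(cls), nPredictedEssential = ness,
                       nPredictedNonEssential = length(cls) - ness))
}

#' Flatten a screen to a data.frame
#'
#' One row per TU with collapsed orphaned demands, essential elements
#' (`gene (ANTICODON)` style) and copy fractions (`aa-ANT in/genome`).
#'
#' @param x A [TUScreen-class].
#' @param row.names,optional,... Ignored (S3 compatibility).
#' @return data.frame with columns `tu_id`, `status`, `orphaned_demands`,
#'   `essential_elements`, `copy_fractions`.
#' @method as.data.frame TUScreen
#' @export
as.data.frame.TUScreen <- function(x, row.names = NULL, optional = FALSE,
                                   ...) {
    rows <- lapply(x@classifications, function(cl) {
        ee <- cl@essentialElements
        cf <- cl@copyFractions
        data.frame(
            tu_id = cl@tuId, status = cl@status,
            orphaned_demands = paste(cl@orphanedDemands, collapse = ";"),
            essential_elements = paste(
                sprintf("%s (%s)", ee$gene, ee$anticodon), collapse = ", "),
            copy_fractions = paste(
                sprintf("%s-%s %d/%d", cf$amino_acid, cf$anticodon,
                        cf$in_tu, cf$genome), collapse = "; "),
            stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

setMethod("as.data.frame", "TUScreen", as.data.frame.TUScreen)

#' Write screen reports
#'
#' TSV (one row per TU) and, optionally, nested JSON.
#'
#' @param screen A [TUScreen-class].
#' @param tsv,json Output paths (`NULL` to skip one of them).
#' @return Invisibly, the flattened data.frame.
#' @export
writeScreenReport <- function(screen, tsv = NULL, json = NULL) {
    stopifnot(is(screen, "TUScreen"))
    df <- as.data.frame(screen)
    if (!is.null(tsv))
        utils::write.table(df, tsv, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    if (!is.null(json)) {
        obj <- list(summary = screen@summary,
                    classifications = lapply(screen@classifications,
            function(cl) list(tu_id = cl@tuId, status = cl@status,
                              orphaned_demands = cl@orphanedDemands,
                              essential_elements = cl@essentialElements,
                              copy_fractions = cl@copyFractions)))
        writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE),
                   json)
    }
    invisible(df)
}
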