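#' @import methods
NULL

.RNA_BASES <- c("A", "C", "G", "U")

#' WobbleRuleSet: anticodon position-34 decoding rules
#'
#' Maps a wobble key -- the identity of the anticodon base at tRNA position
#' 34, or the label of its modification (e.g. \code{cmo5U}, \code{k2C},
#' \code{I}) -- to the set of codon third-position bases that base can read.
#' Positions 35 and 36 always pair by strict Watson-Crick complementarity;
#' only position 34 wobbles.
#'
#' @slot rules Named list; each element a nonempty character vector over
#'   \code{A/C/G/U} giving the readable codon third-position bases.
#' @slot version Single string labelling the rule table.
#' @seealso [defaultWobbleRules()], [readWobbleRules()], [decodes()]
#' @exportClass WobbleRuleSet
setClass("WobbleRuleSet",
    slots = c(rules = "list", version = "character"))

setValidity("WobbleRuleSet", function(object) {
    msg <- character()
    if (length(object@version) != 1L || is.na(object@version))
        msg <- c(msg, "'version' must be a single string")
    r <- object@rules
    if (length(r) == 0L || is.null(names(r)) || any(names(r) == ""))
        msg <- c(msg, "'rules' must be a nonempty named list")
    for (k in names(r)) {
        b <- r[[k]]
        if (!is.character(b) || length(b) == 0L)
            msg <- c(msg, sprintf("rule '%s' must map to a nonempty base set", k))
        else if (!all(b %in% .RNA_BASES))
            msg <- c(msg, sprintf("rule '%s' contains bases outside A/C/G/U", k))
    }
    if (length(msg)) msg else TRUE
})

#' TRNARegistry: the tRNA gene / transcription-unit universe
#'
#' Holds one row per tRNA gene (name, amino acid, anticodon written 5'->3',
#' optional position-34 modification label, functional class, transcription
#' unit membership) together with the transcription-unit (TU) table. The
#' TU is the unit of chromosomal deletion.
#'
#' @slot genes data.frame with columns \code{gene}, \code{amino_acid},
#'   \code{anticodon}, \code{modification} (\code{""} when unmodified),
#'   \code{class} (one of \code{elongator}, \code{initiator},
#'   \code{selenocysteine}) and \code{tu_id}.
#' @slot tus data.frame with columns \code{tu_id}, \code{display_name} and
#'   logical \code{non_trna} (TRUE when the TU also carries non-tRNA genes,
#'   e.g. the rRNA operons).
#' @slot provenance Character vector of free-text provenance notes.
#' @seealso [loadRegistry()], [screenTUs()]
#' @exportClass TRNARegistry
setClass("TRNARegistry",
    slots = c(genes = "data.frame", tus = "data.frame",
              provenance = "character"))

.GENE_COLS <- c("gene", "amino_acid", "anticodon", "modification",
                "class", "tu_id")
.CLASSES <- c("elongator", "initiator", "selenocysteine")

.validAnticodon <- function(x) {
    nchar(x) == 3L &
        vapply(strsplit(x, ""), function(b) all(b %in% .RNA_BASES), logical(1))
}

setValidity("TRNARegistry", function(object) {
    msg <- character()
    g <- object@genes
    tu <- object@tus
    if (!all(.GENE_COLS %in% names(g)))
        return(paste("missing gene columns:",
                     paste(setdiff(.GENE_COLS, names(g)), collapse = ", ")))
    if (!all(c("tu_id", "display_name", "non_trna") %in% names(tu)))
        return("TU table needs columns tu_id, display_name, non_trna")
    if (anyDuplicated(g$gene))
        msg <- c(msg, paste("duplicate gene name(s):",
                 paste(unique(g$gene[duplicated(g$gene)]), collapse = ", ")))
    if (anyDuplicated(tu$tu_id))
        msg <- c(msg, "duplicate tu_id in TU table")
    bad <- !.validAnticodon(g$anticodon)
    if (any(bad))
        msg <- c(msg, paste("invalid anticodon for gene(s):",
                 paste(g$gene[bad], collapse = ", ")))
    if (!all(g$class %in% .CLASSES))
        msg <- c(msg, "gene class must be elongator/initiator/selenocysteine")
    dangling <- setdiff(g$tu_id, tu$tu_id)
    if (length(dangling))
        msg <- c(msg, paste("dangling tu_id:", paste(dangling, collapse = ", ")))
    empty <- setdiff(tu$tu_id, g$tu_id)
    if (length(empty))
        msg <- c(msg, paste("TU(s) without genes:",
                 paste(empty, collapse = ", ")))
    if (any(g$class == "initiator" & g$amino_acid != "Met"))
        msg <- c(msg, "functional class 'initiator' is reserved for fMet genes")
    if (length(msg)) msg else TRUE
})

#' TUClassification: verdict of the in-silico deletion of one TU
#'
#' @slot tuId The classified TU.
#' @slot status \code{"predicted-essential"} or
#'   \code{"predicted-non-essential"}.
#' @slot orphanedDemands Decoding demands (sense codons, plus
#'   \code{"initiation"}) left uncovered when the TU is removed; empty for
#'   non-essential TUs.
#' @slot essentialElements data.frame (\code{gene}, \code{anticodon}) of
#'   genes inside the TU that serve at least one orphaned demand.
#' @slot copyFractions data.frame (\code{amino_acid}, \code{anticodon},
#'   \code{in_tu}, \code{genome}): how many genome-wide copies of each
#'   isoacceptor in the TU sit inside it.
#' @seealso [classifyTU()]
#' @exportClass TUClassification
setClass("TUClassification",
    slots = c(tuId = "character", status = "character",
              orphanedDemands = "character",
              essentialElements = "data.frame",
              copyFractions = "data.frame"))

setValidity("TUClassification", function(object) {
    msg <- character()
    if (!object@status %in% c("predicted-essential", "predicted-non-essential"))
        msg <- c(msg, "unknown status")
    ess <- object@status == "predicted-essential"
    if (ess != (length(object@orphanedDemands) > 0L))
        msg <- c(msg, "status must be essential iff orphaned demands nonempty")
    if (ess != (nrow(object@essentialElements) > 0L))
        msg <- c(msg, "essential elements nonempty iff essential")
    if (length(msg)) msg else TRUE
})

#' TUScreen: one classification per TU of a registry
#'
#' @slot classifications List of [TUClassification-class], in registry TU
#'   order.
#' @slot summary List with \code{nTUs}, \code{nPredictedEssential},
#'   \code{nPredictedNonEssential}.
#' @seealso [screenTUs()]
#' @exportClass TUScreen
setClass("TUScreen",
    slots = c(classifications = "list", summary = "list"))

setValidity("TUScreen", function(object) {
    ok <- all(vapply(object@classifications, is, logical(1), "TUClassification"))
    if (!ok) return("all elements must be TUClassification")
    n <- length(object@classifications)
    s <- object@summary
    if (!identical(s$nTUs, n))
        return("summary nTUs disagrees with classification count")
    if (s$nPredictedEssential + s$nPredictedNonEssential != n)
        return("summary counts do not partition the TUs")
    TRUE
})

#' ConcordanceReport: predictions vs experimental outcomes
#'
#' @slot nTUs Number of TUs compared.
#' @slot nConcordant TUs where prediction and observation agree.
#' @slot mismatches data.frame (\code{tu_id}, \code{predicted},
#'   \code{observed}).
#' @seealso [concordance()]
#' @exportClass ConcordanceReport
setClass("ConcordanceReport",
    slots = c(nTUs = "integer", nConcordant = "integer",
              mismatches = "data.frame"))

setValidity("ConcordanceReport", function(object) {
    if (object@nConcordant + nrow(object@mismatches) != object@nTUs)
        return("concordant + mismatches must equal nTUs")
    TRUE
})

#' DEGThresholds: cut-offs for differential-expression calling
#'
#' @slot lfcCut Positive log2 fold-change bound (inclusive), default 1.5.
#' @slot fdrCut FDR bound in (0,1) (strict), default 0.05.
#' @seealso [callDEGs()]
#' @exportClass DEGThresholds
setClass("DEGThresholds", slots = c(lfcCut = "numeric", fdrCut = "numeric"))

setValidity("DEGThresholds", function(object) {
    msg <- character()
    if (length(object@lfcCut) != 1L || !is.finite(object@lfcCut) ||
        object@lfcCut <= 0)
        msg <- c(msg, "lfcCut must be a single positive number")
    if (length(object@fdrCut) != 1L || !is.finite(object@fdrCut) ||
        object@fdrCut <= 0 || object@fdrCut >= 1)
        msg <- c(msg, "fdrCut must lie strictly between 0 and 1")
    if (length(msg)) msg else TRUE
})

#' DEGCallSet: up/down gene sets called at fixed thresholds
#'
#' @slot up Genes with log2FC >= +lfcCut and FDR < fdrCut.
#' @slot down Genes with log2FC <= -lfcCut and FDR < fdrCut.
#' @slot thresholds The [DEGThresholds-class] used.
#' @seealso [callDEGs()], [overlapDEGs()]
#' @exportClass DEGCallSet
setClass("DEGCallSet",
    slots = c(up = "character", down = "character",
              thresholds = "DEGThresholds"))

setValidity("DEGCallSet", function(object) {
    if (length(intersect(object@up, object@down)))
        return("a gene cannot be both up- and down-regulated")
    TRUE
})

#' DEGOverlap: direction-resolved overlap of two call sets
#'
#' @slot common data.frame (\code{gene_id}, \code{direction_a},
#'   \code{direction_b}).
#' @slot nSameDirection Count of common genes regulated in the same
#'   direction in both strains.
#' @slot nOppositeDirection Count regulated in opposite directions.
#' @seealso [overlapDEGs()]
#' @exportClass DEGOverlap
setClass("DEGOverlap",
    slots = c(common = "data.frame", nSameDirection = "integer",
              nOppositeDirection = "integer"))

setValidity("DEGOverlap", function(object) {
    if (object@nSameDirection + object@nOppositeDirection !=
        nrow(object@common))
        return("direction counts must partition the common genes")
    TRUE
})
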