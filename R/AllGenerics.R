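#' @include AllClasses.R
NULL

#' Accessors for the core classes
#'
#' Small accessor generics so that slot layout stays an implementation
#' detail: `rules()`/`ruleVersion()` for [WobbleRuleSet-class];
#' `genes()`/`tus()`/`nGenes()`/`nTUs()`/`provenance()` for
#' [TRNARegistry-class]; `tuStatus()`, `orphanedDemands()`,
#' `essentialElements()`, `copyFractions()` for [TUClassification-class];
#' `classifications()` and `screenSummary()` for [TUScreen-class];
#' `mismatches()` for [ConcordanceReport-class]; `upGenes()`, `downGenes()`
#' and `degGenes()` for [DEGCallSet-class]; `commonGenes()` for
#' [DEGOverlap-class].
#'
#' @param x An object of the documented class.
#' @return The slot contents (a list, data.frame, character vector or
#'   count, as named).
#' @name accessors
#' @aliases rules ruleVersion genes tus nGenes nTUs provenance tuStatus
#'   orphanedDemands essentialElements copyFractions classifications
#'   screenSummary mismatches upGenes downGenes degGenes commonGenes
#' @examples
#' reg <- loadRegistry("mg1655")
#' nGenes(reg)
#' nTUs(reg)
NULL

#' @rdname accessors
#' @export
setGeneric("rules", function(x) standardGeneric("rules"))
#' @rdname accessors
#' @export
setGeneric("ruleVersion", function(x) standardGeneric("ruleVersion"))
#' @rdname accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
#' @rdname accessors
#' @export
setGeneric("tus", function(x) standardGeneric("tus"))
#' @rdname accessors
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))
#' @rdname accessors
#' @export
setGeneric("nTUs", function(x) standardGeneric("nTUs"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("tuStatus", function(x) standardGeneric("tuStatus"))
#' @rdname accessors
#' @export
setGeneric("orphanedDemands", function(x) standardGeneric("orphanedDemands"))
#' @rdname accessors
#' @export
setGeneric("essentialElements",
           function(x) standardGeneric("essentialElements"))
#' @rdname accessors
#' @export
setGeneric("copyFractions", function(x) standardGeneric("copyFractions"))
#' @rdname accessors
#' @export
setGeneric("classifications", function(x) standardGeneric("classifications"))
#' @rdname accessors
#' @export
setGeneric("screenSummary", function(x) standardGeneric("screenSummary"))
#' @rdname accessors
#' @export
setGeneric("mismatches", function(x) standardGeneric("mismatches"))
#' @rdname accessors
#' @export
setGeneric("upGenes", function(x) standardGeneric("upGenes"))
#' @rdname accessors
#' @export
setGeneric("downGenes", function(x) standardGeneric("downGenes"))
#' @rdname accessors
#' @export
setGeneric("degGenes", function(x) standardGeneric("degGenes"))
#' @rdname accessors
#' @export
setGeneric("commonGenes", function(x) standardGeneric("commonGenes"))

setMethod("rules", "WobbleRuleSet", function(x) x@rules)
setMethod("ruleVersion", "WobbleRuleSet", function(x) x@version)
setMethod("genes", "TRNARegistry", function(x) x@genes)
setMethod("tus", "TRNARegistry", function(x) x@tus)
setMethod("nGenes", "TRNARegistry", function(x) nrow(x@genes))
setMethod("nTUs", "TRNARegistry", function(x) nrow(x@tus))
setMethod("provenance", "TRNARegistry", function(x) x@provenance)
setMethod("tuStatus", "TUClassification", function(x) x@status)
setMethod("orphanedDemands", "TUClassification", function(x) x@orphanedDemands)
setMethod("essentialElements", "TUClassification",
          function(x) x@essentialElements)
setMethod("copyFractions", "TUClassification", function(x) x@copyFractions)
setMethod("classifications", "TUScreen", function(x) x@classifications)
setMethod("screenSummary", "TUScreen", function(x) x@summary)
setMethod("mismatches", "ConcordanceReport", function(x) x@mismatches)
setMethod("upGenes", "DEGCallSet", function(x) x@up)
setMethod("downGenes", "DEGCallSet", function(x) x@down)
setMethod("degGenes", "DEGCallSet", function(x) sort(c(x@up, x@down)))
setMethod("commonGenes", "DEGOverlap", function(x) x@common$gene_id)

setMethod("show", "WobbleRuleSet", function(object) {
    cat("WobbleRuleSet '", object@version, "' with ",
        length(object@rules), " keys\n", sep = "")
    for (k in names(object@rules))
        cat("  ", format(k, width = 7), "-> ",
            paste(object@rules[[k]], collapse = ","), "\n", sep = "")
})

setMethod("show", "TRNARegistry", function(object) {
    cat("TRNARegistry:", nrow(object@genes), "tRNA genes in",
        nrow(object@tus), "transcription units\n")
    cls <- table(object@genes$class)
    cat("  classes:", paste(names(cls), cls, sep = "=", collapse = ", "), "\n")
    cat("  provenance:", object@provenance[1], "\n")
})

setMethod("show", "TUClassification", function(object) {
    cat("TU", object@tuId, "->", object@status, "\n")
    if (length(object@orphanedDemands)) {
        cat("  orphaned demands:",
            paste(object@orphanedDemands, collapse = ", "), "\n")
        cat("  essential elements:",
            paste(sprintf("%s (%s)", object@essentialElements$gene,
                          object@essentialElements$anticodon),
                  collapse = ", "), "\n")
    }
})

setMethod("show", "TUScreen", function(object) {
    s <- object@summary
    cat("TUScreen:", s$nTUs, "TUs |", s$nPredictedEssential,
        "predicted-essential,", s$nPredictedNonEssential,
        "predicted-non-essential\n")
    ess <- vapply(object@classifications, function(x)
        x@status == "predicted-essential", logical(1))
    if (any(ess))
        cat("  essential:", paste(vapply(object@classifications[ess],
            function(x) x@tuId, character(1)), collapse = ", "), "\n")
})

setMethod("show", "ConcordanceReport", function(object) {
    cat("ConcordanceReport:", object@nConcordant, "of", object@nTUs,
        "TUs concordant;", nrow(object@mismatches), "mismatch(es)\n")
    if (nrow(object@mismatches)) {
        m <- object@mismatches
        for (i in seq_len(nrow(m)))
            cat("  ", m$tu_id[i], ": predicted ", m$predicted[i],
                ", observed ", m$observed[i], "\n", sep = "")
    }
})

setMethod("show", "DEGCallSet", function(object) {
    cat("DEGCallSet:", length(object@up), "up,", length(object@down),
        "down (|log2FC| >=", object@thresholds@lfcCut, ", FDR <",
        object@thresholds@fdrCut, ")\n")
})

setMethod("show", "DEGOverlap", function(object) {
    cat("DEGOverlap:", nrow(object@common), "common genes (",
        object@nSameDirection, "same-direction,",
        object@nOppositeDirection, "opposite )\n")
})
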