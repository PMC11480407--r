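#' @include AllClasses.R essentiality.R
NULL

#' Load experimentally determined TU essentiality outcomes
#'
#' Reads the outcomes TSV (columns `tu_id`, `essential_observed` as 0/1,
#' optional `complementation_note` and `impairment_note`).
#' `source = "mg1655"` loads the packaged table of the deletion screen in
#' E. coli MG1655 (DE3): all 43 tRNA TUs, 10 of which could only be
#' deleted in the presence of a complementing tRNA plasmid (essential)
#' while 33 could be deleted outright. Notes record the two TUs whose
#' complementing plasmid required the strong lpp promoter (argU, rrnC) and
#' the strongly growth-impaired viable deletions (alaWX, valVW, metZWV);
#' both annotations are carried uninterpreted.
#'
#' @param source Path to an outcomes TSV or the builtin `"mg1655"`.
#' @param registry Optional [TRNARegistry-class]; when supplied, the
#'   outcome TU ids must match the registry TU ids exactly.
#' @return data.frame with columns `tu_id`, `essential_observed`
#'   (logical), `complementation_note`, `impairment_note`.
#' @examples
#' out <- loadOutcomes("mg1655")
#' sum(out$essential_observed)   # 10
#' sum(!out$essential_observed)  # 33
#' @export
loadOutcomes <- function(source = "mg1655", registry = NULL) {
    if (identical(source, "mg1655"))
        source <- system.file("extdata", "mg1655_tu_outcomes.tsv",
                              package = "tRNAessentials", mustWork = TRUE)
    if (!file.exists(source))
        stop("outcomes source not found: ", source, call. = FALSE)
    out <- utils::read.delim(source, colClasses = "character",
                             na.strings = NULL)
    if (!all(c("tu_id", "essential_observed") %in% names(out)))
        stop("outcomes TSV needs columns tu_id, essential_observed: ",
             source, call. = FALSE)
    if (nrow(out) == 0L)
        stop("outcomes table is empty: ", source, call. = FALSE)
    if (anyDuplicated(out$tu_id))
        stop("duplicate tu_id in outcomes table", call. = FALSE)
    if (!all(out$essential_observed %in% c("0", "1")))
        stop("essential_observed must be 0/1", call. = FALSE)
    out$essential_observed <- out$essential_observed == "1"
    for (col in c("complementation_note", "impairment_note")) {
        if (is.null(out[[col]])) out[[col]] <- ""
        out[[col]][is.na(out[[col]])] <- ""
    }
    out <- out[, c("tu_id", "essential_observed", "complementation_note",
                   "impairment_note")]
    if (!is.null(registry)) {
        stopifnot(is(registry, "TRNARegistry"))
        extra <- setdiff(out$tu_id, registry@tus$tu_id)
        missing <- setdiff(registry@tus$tu_id, out$tu_id)
        if (length(extra) || length(missing))
            stop("outcomes/registry TU sets differ; only in outcomes: {",
                 paste(extra, collapse = ", "), "}; only in registry: {",
                 paste(missing, collapse = ", "), "}", call. = FALSE)
    }
    out
}

.predStatus <- function(predictions) {
    if (is(predictions, "TUScreen"))
        predictions <- predictions@classifications
    if (!is.list(predictions) ||
        !all(vapply(predictions, is, logical(1), "TUClassification")))
        stop("'predictions' must be a TUScreen or a list of ",
             "TUClassification objects", call. = FALSE)
    data.frame(
        tu_id = vapply(predictions, function(x) x@tuId, character(1)),
        predicted_essential = vapply(predictions, function(x)
            x@status == "predicted-essential", logical(1)),
        stringsAsFactors = FALSE)
}

#' Concordance between predictions and experimental outcomes
#'
#' Pairs each TU's predicted status with its observed essentiality and
#' reports the mismatches. On the packaged MG1655 fixture the screen and
#' the experiment disagree on exactly two TUs -- ileX and
#' lysT-valT-lysW-valZ-lysYZQ, both predicted non-essential because a
#' decoder copy remains (ileY, resp. lysV and valUXY) yet observed
#' essential -- a copy-number/expression effect outside the coverage
#' criterion.
#'
#' @param predictions A [TUScreen-class] or list of
#'   [TUClassification-class].
#' @param outcomes data.frame as returned by [loadOutcomes()].
#' @return A [ConcordanceReport-class].
#' @examples
#' reg <- loadRegistry("mg1655")
#' concordance(screenTUs(reg), loadOutcomes("mg1655"))
#' @export
concordance <- function(predictions, outcomes) {
    pred <- .predStatus(predictions)
    if (!is.data.frame(outcomes) ||
        !all(c("tu_id", "essential_observed") %in% names(outcomes)))
        stop("'outcomes' must have columns tu_id, essential_observed",
             call. = FALSE)
    onlyP <- setdiff(pred$tu_id, outcomes$tu_id)
    onlyO <- setdiff(outcomes$tu_id, pred$tu_id)
    if (length(onlyP) || length(onlyO))
        stop("prediction/outcome TU sets differ; only predicted: {",
             paste(onlyP, collapse = ", "), "}; only observed: {",
             paste(onlyO, collapse = ", "), "}", call. = FALSE)
    obs <- outcomes$essential_observed[match(pred$tu_id, outcomes$tu_id)]
    dis <- pred$predicted_essential != obs
    mm <- data.frame(
        tu_id = pred$tu_id[dis],
        predicted = ifelse(pred$predicted_essential[dis],
                           "essential", "non-essential"),
        observed = ifelse(obs[dis], "essential", "non-essential"),
        stringsAsFactors = FALSE)
    mm <- mm[order(mm$tu_id), , drop = FALSE]
    rownames(mm) <- NULL
    new("ConcordanceReport", nTUs = nrow(pred),
        nConcordant = as.integer(sum(!dis)), mismatches = mm)
}
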