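#' @include AllClasses.R registry.R essentiality.R validation.R dge.R
NULL

#' Run the full registry-to-report analysis
#'
#' Composes the stages end to end: load the registry and wobble rules,
#' screen every TU, compare with the experimental outcomes, call DEGs in
#' each supplied per-gene table, overlap the first two call sets and
#' bucket the common genes by ontology label. All reports are written
#' under `outDir` (TSV for tables, JSON for nested objects) plus a
#' `summary.json` with the headline counts; outputs are byte-identical
#' across reruns on identical inputs.
#'
#' On the packaged fixtures the summary reports 43 TUs, 86 genes,
#' 8 predicted / 10 observed essential TUs, 2 prediction mismatches and
#' 12 overlapping DEGs.
#'
#' @param registry Registry source for [loadRegistry()].
#' @param outcomes Outcomes source for [loadOutcomes()].
#' @param dgeTables Named list of at least two DGE table sources for
#'   [readDGETable()]; the first two are overlapped.
#' @param ruleset A [WobbleRuleSet-class] or a path readable by
#'   [readWobbleRules()].
#' @param thresholds A [DEGThresholds-class].
#' @param outDir Output directory (created if missing).
#' @return Invisibly, a list with `screen`, `concordance`, `calls`,
#'   `overlap`, `labelSummary` and `summary`.
#' @examples
#' bundle <- runFullAnalysis(outDir = tempfile("reports"))
#' bundle$summary$n_overlap_genes  # 12
#' @export
runFullAnalysis <- function(registry = "mg1655", outcomes = "mg1655",
                            dgeTables = list(alaWX = "alaWX_example",
                                             valVW = "valVW_example"),
                            ruleset = defaultWobbleRules(),
                            thresholds = degThresholds(),
                            outDir = "trna-reports") {
    if (is.character(ruleset)) ruleset <- readWobbleRules(ruleset)
    stopifnot(is(ruleset, "WobbleRuleSet"), is(thresholds, "DEGThresholds"))
    if (length(dgeTables) < 2L || is.null(names(dgeTables)))
        stop("'dgeTables' must be a named list of at least two tables",
             call. = FALSE)
    # resolve all inputs before any computation
    reg <- loadRegistry(registry)
    out <- loadOutcomes(outcomes, registry = reg)
    records <- lapply(dgeTables, readDGETable)
    if (!dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)

    scr <- screenTUs(reg, ruleset)
    writeScreenReport(scr, tsv = file.path(outDir, "screen_report.tsv"),
                      json = file.path(outDir, "screen_report.json"))

    conc <- concordance(scr, out)
    writeLines(jsonlite::toJSON(list(
        n_tus = conc@nTUs, n_concordant = conc@nConcordant,
        mismatches = conc@mismatches), auto_unbox = TRUE, pretty = TRUE),
        file.path(outDir, "concordance.json"))

    calls <- lapply(records, callDEGs, thresholds = thresholds)
    ov <- overlapDEGs(calls[[1]], calls[[2]])
    utils::write.table(ov@common, file.path(outDir, "deg_overlap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    labels <- do.call(rbind, lapply(records, function(r)
        r[, c("gene_id", "label")]))
    labSum <- summarizeOverlapByLabel(ov, labels)
    utils::write.table(labSum, file.path(outDir, "overlap_by_label.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    summary <- list(
        n_tus = nTUs(reg), n_genes = nGenes(reg),
        n_predicted_essential = scr@summary$nPredictedEssential,
        n_observed_essential = sum(out$essential_observed),
        n_mismatches = nrow(conc@mismatches),
        n_degs = lapply(calls, function(x) length(c(x@up, x@down))),
        n_overlap_genes = nrow(ov@common))
    writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, pretty = TRUE),
               file.path(outDir, "summary.json"))

    invisible(list(screen = scr, concordance = conc, calls = calls,
                   overlap = ov, labelSummary = labSum, summary = summary))
}
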