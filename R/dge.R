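#' @include AllClasses.R
NULL

#' Construct DEG-calling thresholds
#'
#' Defaults are the study thresholds: |log2FC| >= 1.5 (inclusive) and
#' FDR < 0.05 (strict).
#'
#' @param lfcCut Positive log2 fold-change bound.
#' @param fdrCut FDR bound in (0,1).
#' @return A [DEGThresholds-class].
#' @examples
#' degThresholds()
#' @export
degThresholds <- function(lfcCut = 1.5, fdrCut = 0.05) {
    new("DEGThresholds", lfcCut = as.numeric(lfcCut),
        fdrCut = as.numeric(fdrCut))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values
#' (delegated to [stats::p.adjust()]); the result is order-preserving
#' with respect to the input positions and never smaller than the input.
#'
#' @param pvalues Nonempty numeric vector of p-values in \[0,1\].
#' @return Numeric vector of adjusted values (same length/order).
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(pvalues) {
    if (!is.numeric(pvalues) || length(pvalues) == 0L)
        stop("'pvalues' must be a nonempty numeric vector", call. = FALSE)
    if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
        stop("p-values must lie in [0, 1]", call. = FALSE)
    stats::p.adjust(pvalues, method = "BH")
}

#' Read a per-gene differential-expression table
#'
#' TSV (or CSV, by file extension) with header columns `gene_id`,
#' `log2fc`, `fdr`, and optionally `pvalue` and `label` (a gene-ontology
#' or similar bucket). Two packaged worked-example tables,
#' `"alaWX_example"` and `"valVW_example"`, carry the twelve genes found
#' differentially expressed in both the \eqn{\Delta}alaWX and
#' \eqn{\Delta}valVW deletion strains (log2 fold changes as observed in
#' the published screen) plus sub-threshold rows for the remaining
#' alanine/valine tRNA genes; FDR values on these fixtures are synthetic
#' below-threshold stand-ins, as only the < 0.05 bound is published.
#'
#' @param source File path, or one of the builtin identifiers
#'   `"alaWX_example"`, `"valVW_example"`.
#' @return data.frame with columns `gene_id`, `log2fc`, `pvalue`, `fdr`,
#'   `label`.
#' @examples
#' head(readDGETable("alaWX_example"))
#' @export
readDGETable <- function(source) {
    builtin <- c(alaWX_example = "deg_alaWX_example.tsv",
                 valVW_example = "deg_valVW_example.tsv")
    if (is.character(source) && length(source) == 1L &&
        source %in% names(builtin))
        source <- system.file("extdata", builtin[[source]],
                              package = "tRNAessentials", mustWork = TRUE)
    if (!file.exists(source))
        stop("DGE table not found: ", source, call. = FALSE)
    reader <- if (grepl("\\.csv$", source)) utils::read.csv
              else utils::read.delim
    d <- reader(source, stringsAsFactors = FALSE)
    need <- c("gene_id", "log2fc", "fdr")
    miss <- setdiff(need, names(d))
    if (length(miss))
        stop("DGE table ", source, " lacks column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    if (is.null(d$pvalue)) d$pvalue <- NA_real_
    if (is.null(d$label)) d$label <- ""
    d$label[is.na(d$label)] <- ""
    bad <- !is.na(d$fdr) & (d$fdr < 0 | d$fdr > 1)
    if (any(bad))
        stop("fdr outside [0,1] for gene(s): ",
             paste(d$gene_id[bad], collapse = ", "), call. = FALSE)
    d[, c("gene_id", "log2fc", "pvalue", "fdr", "label")]
}

#' Call differentially expressed genes
#'
#' A gene is called up-regulated when `log2fc >= +lfcCut` and
#' `fdr < fdrCut`, down-regulated when `log2fc <= -lfcCut` and
#' `fdr < fdrCut`; anything else is not a DEG. Tightening either
#' threshold can only shrink the call sets.
#'
#' @param records data.frame with columns `gene_id`, `log2fc`, `fdr`
#'   (e.g. from [readDGETable()]).
#' @param thresholds A [DEGThresholds-class].
#' @return A [DEGCallSet-class].
#' @examples
#' calls <- callDEGs(readDGETable("alaWX_example"))
#' length(degGenes(calls))  # 12
#' @export
callDEGs <- function(records, thresholds = degThresholds()) {
    stopifnot(is(thresholds, "DEGThresholds"))
    if (!is.data.frame(records) ||
        !all(c("gene_id", "log2fc", "fdr") %in% names(records)))
        stop("'records' must have columns gene_id, log2fc, fdr",
             call. = FALSE)
    noFdr <- is.na(records$fdr)
    if (any(noFdr))
        stop("missing fdr for gene(s): ",
             paste(records$gene_id[noFdr], collapse = ", "), call. = FALSE)
    sig <- records$fdr < thresholds@fdrCut
    up <- records$gene_id[sig & records$log2fc >= thresholds@lfcCut]
    down <- records$gene_id[sig & records$log2fc <= -thresholds@lfcCut]
    new("DEGCallSet", up = up, down = down, thresholds = thresholds)
}

#' Direction-resolved overlap of two DEG call sets
#'
#' The common genes are the intersection of the two strains' DEG sets
#' (up or down in each); per-strain directions are retained and the
#' same-direction / opposite-direction counts reported.
#'
#' @param a,b [DEGCallSet-class] objects over the same gene universe.
#' @return A [DEGOverlap-class]; `common` is sorted by gene id.
#' @examples
#' ov <- overlapDEGs(callDEGs(readDGETable("alaWX_example")),
#'                   callDEGs(readDGETable("valVW_example")))
#' length(commonGenes(ov))  # 12
#' @export
overlapDEGs <- function(a, b) {
    stopifnot(is(a, "DEGCallSet"), is(b, "DEGCallSet"))
    common <- sort(intersect(c(a@up, a@down), c(b@up, b@down)))
    dirA <- ifelse(common %in% a@up, "up", "down")
    dirB <- ifelse(common %in% b@up, "up", "down")
    df <- data.frame(gene_id = common, direction_a = dirA,
                     direction_b = dirB, stringsAsFactors = FALSE)
    new("DEGOverlap", common = df,
        nSameDirection = as.integer(sum(dirA == dirB)),
        nOppositeDirection = as.integer(sum(dirA != dirB)))
}

#' Count common DEGs per ontology label and direction
#'
#' Buckets the commonly regulated genes by their ontology label.
#' Direction is the shared one for concordant genes and `"discordant"`
#' otherwise; genes without a label fall into an `"unlabelled"` bucket.
#'
#' @param overlap A [DEGOverlap-class].
#' @param records data.frame with `gene_id` and `label` columns supplying
#'   the labels (e.g. a row-bound pair of [readDGETable()] results;
#'   the first label seen per gene wins).
#' @return data.frame `label`, `direction`, `n`, sorted by label then
#'   direction.
#' @examples
#' a <- readDGETable("alaWX_example"); b <- readDGETable("valVW_example")
#' ov <- overlapDEGs(callDEGs(a), callDEGs(b))
#' summarizeOverlapByLabel(ov, rbind(a, b))
#' @export
summarizeOverlapByLabel <- function(overlap, records) {
    stopifnot(is(overlap, "DEGOverlap"))
    if (!is.data.frame(records) ||
        !all(c("gene_id", "label") %in% names(records)))
        stop("'records' must have columns gene_id, label", call. = FALSE)
    cm <- overlap@common
    if (nrow(cm) == 0L)
        return(data.frame(label = character(), direction = character(),
                          n = integer(), stringsAsFactors = FALSE))
    lab <- records$label[match(cm$gene_id, records$gene_id)]
    lab[is.na(lab) | lab == ""] <- "unlabelled"
    dir <- ifelse(cm$direction_a == cm$direction_b, cm$direction_a,
                  "discordant")
    agg <- stats::aggregate(list(n = lab),
                            by = list(label = lab, direction = dir), length)
    agg <- agg[order(agg$label, agg$direction), , drop = FALSE]
    rownames(agg) <- NULL
    agg[, c("label", "direction", "n")]
}

#' Hypergeometric pathway enrichment
#'
#' For each pathway, tests whether the gene set over- or under-represents
#' the pathway's genes relative to the background universe with a
#' one-sided hypergeometric tail ([stats::phyper()]): the enrichment tail
#' when the observed count is at least its expectation, the depletion
#' tail otherwise. P-values are Benjamini-Hochberg adjusted across
#' pathways. No pathway annotation ships with the package; supply your
#' own mapping.
#'
#' @param geneSet Character vector of genes of interest (subset of
#'   `background`).
#' @param annotation Named list: pathway -> character vector of member
#'   genes (each a subset of `background`).
#' @param background Character vector, the gene universe.
#' @param fdrCut Significance cut on the adjusted values (default 0.05).
#' @return data.frame with one row per pathway: `pathway`, `observed`,
#'   `pathway_size`, `expected`, `direction` (`enriched`/`depleted`),
#'   `pvalue`, `fdr`, `significant`; pathways in `annotation` order.
#' @examples
#' bg <- sprintf("g%02d", 1:100)
#' ann <- list(P = bg[1:10])
#' hypergeomEnrichment(bg[c(1, 2, 30, 40, 50)], ann, bg)
#' @export
hypergeomEnrichment <- function(geneSet, annotation, background,
                                fdrCut = 0.05) {
    background <- unique(background)
    geneSet <- unique(geneSet)
    out <- setdiff(geneSet, background)
    if (length(out))
        stop("gene(s) outside background: ",
             paste(out, collapse = ", "), call. = FALSE)
    if (length(annotation) && (is.null(names(annotation)) ||
                               any(names(annotation) == "")))
        stop("'annotation' must be a named list", call. = FALSE)
    for (p in names(annotation)) {
        bad <- setdiff(annotation[[p]], background)
        if (length(bad))
            stop("pathway '", p, "' has gene(s) outside background: ",
                 paste(bad, collapse = ", "), call. = FALSE)
    }
    N <- length(background)
    k <- length(geneSet)
    rows <- lapply(names(annotation), function(p) {
        path <- unique(annotation[[p]])
        m <- length(path)
        q <- length(intersect(geneSet, path))
        expected <- k * m / N
        if (q >= expected) {
            dirn <- "enriched"
            pv <- stats::phyper(q - 1L, m, N - m, k, lower.tail = FALSE)
        } else {
            dirn <- "depleted"
            pv <- stats::phyper(q, m, N - m, k, lower.tail = TRUE)
        }
        data.frame(pathway = p, observed = q, pathway_size = m,
                   expected = expected, direction = dirn, pvalue = pv,
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    if (is.null(res))
        return(data.frame(pathway = character(), observed = integer(),
                          pathway_size = integer(), expected = numeric(),
                          direction = character(), pvalue = numeric(),
                          fdr = numeric(), significant = logical()))
    res$fdr <- bhAdjust(res$pvalue)
    res$significant <- res$fdr < fdrCut
    rownames(res) <- NULL
    res
}
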