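# Brute-force reference implementations, kept independent of the package
# internals: plain string operations, explicit base-pair table, direct
# enumeration over all gene x codon pairs.

oracle_pair <- c(A = "U", U = "A", G = "C", C = "G")

oracle_sense_codons <- function() {
    b <- c("A", "C", "G", "U")
    all64 <- apply(expand.grid(b, b, b), 1L, paste0, collapse = "")
    setdiff(all64, c("UAA", "UAG", "UGA"))
}

# Codons one anticodon (5'->3', positions 34-36) can read under a plain
# rules list (wobble key -> readable codon third-position bases).
oracle_decoded <- function(anticodon, modification, rules_list) {
    b <- strsplit(anticodon, "")[[1]]
    key <- if (!is.na(modification) && nzchar(modification)) modification
           else b[1]
    thirds <- rules_list[[key]]
    if (is.null(thirds)) stop("oracle: unknown wobble key ", key)
    paste0(oracle_pair[[b[3]]], oracle_pair[[b[2]]], thirds)
}

# Essentiality of one TU by direct enumeration over every remaining
# elongator gene and every sense codon, plus the initiator check.
oracle_classify <- function(genes_df, tu_id, rules_list) {
    remain <- genes_df[genes_df$tu_id != tu_id, , drop = FALSE]
    elong <- remain[remain$class == "elongator", , drop = FALSE]
    decoded <- character()
    for (i in seq_len(nrow(elong)))
        decoded <- c(decoded,
                     oracle_decoded(elong$anticodon[i],
                                    elong$modification[i], rules_list))
    orphans <- setdiff(oracle_sense_codons(), decoded)
    init_gone <- !any(remain$class == "initiator")
    list(essential = length(orphans) > 0L || init_gone,
         orphan_codons = sort(orphans), initiation_orphaned = init_gone)
}

# Minimal registry construction for toy cases.
toy_registry <- function(genes_df) {
    if (is.null(genes_df$modification)) genes_df$modification <- ""
    if (is.null(genes_df$class)) genes_df$class <- "elongator"
    tus <- data.frame(tu_id = unique(genes_df$tu_id),
                      display_name = unique(genes_df$tu_id),
                      non_trna = FALSE, stringsAsFactors = FALSE)
    new("TRNARegistry", genes = genes_df, tus = tus, provenance = "toy")
}

# A classification stub, for concordance tests that need hand-made
# predictions.
fake_classification <- function(tu_id, essential) {
    new("TUClassification", tuId = tu_id,
        status = if (essential) "predicted-essential"
                 else "predicted-non-essential",
        orphanedDemands = if (essential) "XXX" else character(),
        essentialElements = if (essential)
            data.frame(gene = "g", anticodon = "AAA",
                       stringsAsFactors = FALSE)
            else data.frame(gene = character(), anticodon = character()),
        copyFractions = data.frame())
}
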