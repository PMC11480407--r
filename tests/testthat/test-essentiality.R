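expected_essential_elements <- list(
    "rrnC" = c("trpT"),
    "argX-hisR-leuT-proM" = c("hisR", "proM"),
    "thrU-tyrU-glyT-thrT" = c("glyT", "thrU"),
    "argU" = c("argU"),
    "metT-leuW-glnUW-metU-glnVX" = c("glnU", "glnV", "glnW", "glnX",
                                     "leuW", "metT", "metU"),
    "serT" = c("serT"),
    "glyW-cysT-leuZ" = c("cysT", "leuZ"),
    "argQZYV-serV" = c("argQ", "argV", "argY", "argZ", "serV"))

test_that("the screen finds exactly the known essential TUs and elements", {
    reg <- loadRegistry("mg1655")
    scr <- screenTUs(reg)
    expect_length(classifications(scr), 43L)
    s <- screenSummary(scr)
    expect_identical(s$nPredictedEssential, 8L)
    expect_identical(s$nPredictedNonEssential, 35L)

    byId <- setNames(classifications(scr),
                     vapply(classifications(scr), function(x) x@tuId, ""))
    for (tu in names(expected_essential_elements)) {
        cl <- byId[[tu]]
        expect_identical(tuStatus(cl), "predicted-essential", info = tu)
        expect_identical(essentialElements(cl)$gene,
                         expected_essential_elements[[tu]], info = tu)
    }
    # the two dosage-driven essential TUs are (by design) predicted viable
    expect_identical(tuStatus(byId[["ileX"]]), "predicted-non-essential")
    expect_identical(tuStatus(byId[["lysT-valT-lysW-valZ-lysYZQ"]]),
                     "predicted-non-essential")
})

test_that("orphaned demands carry the expected codons", {
    reg <- loadRegistry("mg1655")
    expect_identical(orphanedDemands(classifyTU(reg, "serT")), "UCA")
    expect_identical(orphanedDemands(classifyTU(reg, "argU")), "AGA")
    expect_setequal(orphanedDemands(classifyTU(reg, "rrnC")), "UGG")
    expect_setequal(
        orphanedDemands(classifyTU(reg, "argX-hisR-leuT-proM")),
        c("CAC", "CAU", "CCA"))
    expect_error(classifyTU(reg, "noSuchTU"), "noSuchTU")
})

test_that("classification matches the brute-force oracle on all 43 TUs", {
    reg <- loadRegistry("mg1655")
    r <- defaultWobbleRules()
    g <- genes(reg)
    for (tu in tus(reg)$tu_id) {
        cl <- classifyTU(reg, tu, r)
        orc <- oracle_classify(g, tu, rules(r))
        expect_identical(tuStatus(cl) == "predicted-essential",
                         orc$essential, info = tu)
        expect_identical(setdiff(orphanedDemands(cl), "initiation"),
                         orc$orphan_codons, info = tu)
    }
})

test_that("essential elements lie in the TU and each serves an orphan", {
    reg <- loadRegistry("mg1655")
    r <- defaultWobbleRules()
    g <- genes(reg)
    for (cl in classifications(screenTUs(reg, r))) {
        ee <- essentialElements(cl)
        inTU <- g$gene[g$tu_id == cl@tuId]
        expect_true(all(ee$gene %in% inTU), info = cl@tuId)
        orphC <- setdiff(orphanedDemands(cl), "initiation")
        for (gn in ee$gene) {
            row <- g[g$gene == gn, ]
            if (row$class == "initiator") {
                expect_true("initiation" %in% orphanedDemands(cl))
            } else {
                dec <- oracle_decoded(row$anticodon, row$modification,
                                      rules(r))
                expect_true(any(dec %in% orphC), info = gn)
            }
        }
        # copy fractions are bounded by the genome-wide count
        cf <- copyFractions(cl)
        expect_true(all(cf$in_tu >= 1 & cf$in_tu <= cf$genome))
    }
})

test_that("multi-TU coverage gaps generalise the single-TU screen", {
    reg <- loadRegistry("mg1655")
    expect_identical(coverageGap(reg, character()), character())
    expect_identical(coverageGap(reg, "argU"), "AGA")
    # wiping out every alanine decoder orphans the whole GCN box
    gap <- coverageGap(reg, c("alaWX", "rrnA", "rrnD", "rrnH"))
    expect_true(all(c("GCA", "GCC", "GCG", "GCU") %in% gap))
    # deleting both initiator TUs orphans initiation
    expect_true("initiation" %in% coverageGap(reg, c("metY", "metZWV")))
    expect_error(coverageGap(reg, c("argU", "bogus")), "bogus")
})

test_that("sole decoders spread over singleton TUs are all essential", {
    g <- data.frame(
        gene = c("g1", "g2", "g3"),
        amino_acid = c("Phe", "Trp", "His"),
        anticodon = c("GAA", "CCA", "GUG"),
        modification = "", class = "elongator",
        tu_id = c("t1", "t2", "t3"), stringsAsFactors = FALSE)
    reg <- toy_registry(g)
    scr <- screenTUs(reg)
    expect_true(all(vapply(classifications(scr), tuStatus, "") ==
                        "predicted-essential"))
})

test_that("adding an outside gene never makes a viable TU essential", {
    reg <- loadRegistry("mg1655")
    r <- defaultWobbleRules()
    scr <- screenTUs(reg, r)
    viable <- vapply(classifications(scr), function(x)
        x@status == "predicted-non-essential", logical(1))
    viableIds <- tus(reg)$tu_id[viable]
    set.seed(11)
    g <- genes(reg)
    for (rep in 1:5) {
        src <- g[sample(nrow(g), 1), ]
        extra <- src
        extra$gene <- paste0(src$gene, "_dup", rep)
        extra$tu_id <- "newTU"
        g2 <- rbind(g, extra)
        tus2 <- rbind(tus(reg),
                      data.frame(tu_id = "newTU", display_name = "newTU",
                                 non_trna = FALSE))
        reg2 <- new("TRNARegistry", genes = g2, tus = tus2,
                    provenance = "augmented")
        for (tu in viableIds)
            expect_identical(tuStatus(classifyTU(reg2, tu, r)),
                             "predicted-non-essential")
    }
})
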