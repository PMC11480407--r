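test_that("BH adjustment matches the hand-applied step-up formula", {
    expect_identical(bhAdjust(0.5), 0.5)
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    # independent step-up oracle on random vectors
    set.seed(5)
    for (rep in 1:10) {
        p <- runif(sample(1:50, 1))
        n <- length(p)
        o <- order(p)
        sorted <- p[o]
        adj <- rev(cummin(rev(pmin(1, sorted * n / seq_len(n)))))
        expected <- numeric(n)
        expected[o] <- adj
        expect_equal(bhAdjust(p), expected)
        expect_true(all(bhAdjust(p) >= p))
    }
    # monotone on sorted input
    p <- sort(runif(30))
    expect_true(all(diff(bhAdjust(p)) >= 0))
    expect_error(bhAdjust(numeric()), "nonempty")
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DEG calling applies the inclusive-log2FC, strict-FDR rule", {
    a <- readDGETable("alaWX_example")
    b <- readDGETable("valVW_example")
    ca <- callDEGs(a)
    cb <- callDEGs(b)
    expect_true("fimC" %in% upGenes(ca))
    expect_true("flgB" %in% downGenes(cb))
    # sub-threshold tRNA rows are excluded despite tiny FDR
    expect_false(any(c("alaT", "alaU", "alaV") %in% degGenes(ca)))
    expect_false(any(c("valU", "valT") %in% degGenes(cb)))
    # the bound is inclusive at |log2FC| and strict at FDR
    rec <- data.frame(gene_id = c("at", "below", "fdrEq"),
                      log2fc = c(1.5, 1.49, 2.0),
                      fdr = c(0.049, 0.001, 0.05))
    cs <- callDEGs(rec)
    expect_identical(upGenes(cs), "at")
    rec$fdr[1] <- NA
    expect_error(callDEGs(rec), "at")
})

test_that("tightening thresholds never adds called genes", {
    sim <- simulateDGE(nGenes = 500, fracDE = 0.2, seed = 9)
    loose <- callDEGs(sim$records, degThresholds(1.5, 0.05))
    for (th in list(degThresholds(2.0, 0.05), degThresholds(1.5, 0.01),
                    degThresholds(2.5, 0.005))) {
        tight <- callDEGs(sim$records, th)
        expect_true(all(upGenes(tight) %in% upGenes(loose)))
        expect_true(all(downGenes(tight) %in% downGenes(loose)))
    }
    expect_error(degThresholds(-1, 0.05))
    expect_error(degThresholds(1.5, 1.2))
})

test_that("the worked-example overlap is 12 concordant genes", {
    a <- readDGETable("alaWX_example")
    b <- readDGETable("valVW_example")
    ov <- overlapDEGs(callDEGs(a), callDEGs(b))
    expect_identical(nrow(ov@common), 12L)
    expect_identical(ov@nSameDirection, 12L)
    expect_identical(ov@nOppositeDirection, 0L)
    expect_identical(sum(ov@common$direction_a == "up"), 10L)
    expect_identical(sum(ov@common$direction_a == "down"), 2L)
    # extreme fold changes of the worked example
    expect_identical(a$gene_id[which.max(a$log2fc)], "fimC")
    expect_equal(max(a$log2fc), 3.25)
    expect_identical(b$gene_id[which.min(b$log2fc)], "flgB")
    expect_equal(min(b$log2fc), -2.26)
})

test_that("overlap behaves on disjoint, identical and simulated call sets", {
    th <- degThresholds()
    a <- new("DEGCallSet", up = c("g1", "g2"), down = "g3",
             thresholds = th)
    b <- new("DEGCallSet", up = "g9", down = "g8", thresholds = th)
    expect_identical(nrow(overlapDEGs(a, b)@common), 0L)
    self <- overlapDEGs(a, a)
    expect_setequal(commonGenes(self), c("g1", "g2", "g3"))
    expect_identical(self@nSameDirection, 3L)
    # opposite-direction genes are detected
    c2 <- new("DEGCallSet", up = "g3", down = "g1", thresholds = th)
    ovc <- overlapDEGs(a, c2)
    expect_identical(ovc@nOppositeDirection, 2L)
    # |common| <= min of the two call-set sizes on simulated data
    s1 <- simulateDGE(400, 0.15, seed = 21)
    s2 <- simulateDGE(400, 0.15, seed = 22)
    o <- overlapDEGs(callDEGs(s1$records), callDEGs(s2$records))
    expect_lte(nrow(o@common),
               min(length(degGenes(callDEGs(s1$records))),
                   length(degGenes(callDEGs(s2$records)))))
})

test_that("label summary reproduces the functional buckets", {
    a <- readDGETable("alaWX_example")
    b <- readDGETable("valVW_example")
    ov <- overlapDEGs(callDEGs(a), callDEGs(b))
    s <- summarizeOverlapByLabel(ov, rbind(a, b))
    # 6 genes in pilus assembly / protein folding (incl. the fim regulator)
    pilus <- grepl("pilus assembly|protein folding", s$label)
    expect_identical(sum(s$n[pilus]), 6L)
    # the four upregulated 23S rRNA genes form the translation bucket
    expect_identical(s$n[s$label == "translation" & s$direction == "up"],
                     4L)
    # empty overlap -> empty summary; missing labels -> unlabelled bucket
    e <- overlapDEGs(new("DEGCallSet", up = character(),
                         down = character(), thresholds = degThresholds()),
                     callDEGs(b))
    expect_identical(nrow(summarizeOverlapByLabel(e, b)), 0L)
    s2 <- summarizeOverlapByLabel(ov, data.frame(gene_id = "fimC",
                                                 label = "protein folding"))
    expect_true("unlabelled" %in% s2$label)
})

test_that("hypergeometric enrichment equals the exact tail", {
    bg <- sprintf("g%03d", 1:100)
    ann <- list(path10 = bg[1:10])
    # 2 of 5 drawn hitting a 10-gene pathway: exact upper tail by choose()
    gs <- c(bg[1:2], bg[50:52])
    res <- hypergeomEnrichment(gs, ann, bg)
    pExact <- sum(vapply(2:5, function(k)
        choose(10, k) * choose(90, 5 - k), numeric(1))) / choose(100, 5)
    expect_equal(res$pvalue, pExact)
    expect_identical(res$direction, "enriched")
    expect_identical(res$observed, 2L)

    # drawing a full pathway from a large background is maximally enriched
    full <- hypergeomEnrichment(bg[1:10], ann, bg)
    expect_equal(full$pvalue, 1 / choose(100, 10))
    expect_true(full$significant)

    # empty gene set: nothing significant, depletion direction
    none <- hypergeomEnrichment(character(), ann, bg)
    expect_false(any(none$significant))
    expect_error(hypergeomEnrichment("zz", ann, bg), "outside background")
    expect_error(hypergeomEnrichment(bg[1], list(p = "zz"), bg),
                 "outside background")
})
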