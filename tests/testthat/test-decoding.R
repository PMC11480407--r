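test_that("cognate codon is the strict reverse complement", {
    expect_identical(cognateCodon("GGC"), "GCC")  # alaWX anticodon
    expect_identical(cognateCodon("GAC"), "GUC")  # valVW anticodon
    expect_identical(cognateCodon("AAA"), "UUU")
    expect_error(cognateCodon("GG"), "length 3")
    expect_error(cognateCodon("GGT"), "A/C/G/U")
    expect_error(cognateCodon(c("GGC", "GAC")), "single string")
})

test_that("wobble pairing decides decoding per position-34 key", {
    r <- defaultWobbleRules()
    # unmodified G34 reads codon-3 C and U, nothing else
    expect_true(decodes(list(anticodon = "GGC"), "GCU", r))
    expect_true(decodes(list(anticodon = "GGC"), "GCC", r))
    expect_false(decodes(list(anticodon = "GGC"), "GCA", r))
    expect_false(decodes(list(anticodon = "GGC"), "GCG", r))
    # cmo5U-modified U34 reads the whole codon box
    for (cod in c("GCA", "GCC", "GCG", "GCU"))
        expect_true(decodes(list(anticodon = "UGC",
                                 modification = "cmo5U"), cod, r))
    # lysidine restricts CAU to codon-3 A (AUA, not AUG)
    expect_true(decodes(list(anticodon = "CAU", modification = "k2C"),
                        "AUA", r))
    expect_false(decodes(list(anticodon = "CAU", modification = "k2C"),
                         "AUG", r))
    # positions 35/36 are strict: a one-base mismatch in the codon body fails
    expect_false(decodes(list(anticodon = "GGC"), "ACC", r))
    expect_false(decodes(list(anticodon = "GGC"), "GAC", r))
})

test_that("unknown wobble keys raise a configuration error naming the key", {
    r <- defaultWobbleRules()
    expect_error(decodes(list(anticodon = "UGC", modification = "xyzU"),
                         "GCC", r), "xyzU")
    expect_error(decodingTable(data.frame(gene = "g1", anticodon = "UGC",
                                          modification = "weird"), r),
                 "weird")
})

test_that("decoding agrees with brute-force enumeration on the fixture", {
    reg <- loadRegistry("mg1655")
    r <- defaultWobbleRules()
    g <- genes(reg)
    sense <- oracle_sense_codons()
    for (i in sample(nrow(g), 20)) {
        expected <- intersect(
            oracle_decoded(g$anticodon[i], g$modification[i], rules(r)),
            sense)
        got <- sense[vapply(sense, function(cod)
            decodes(g[i, ], cod, r), logical(1))]
        expect_setequal(got, expected)
    }
})

test_that("decoding table covers sense codons only, deterministically", {
    r <- defaultWobbleRules()
    one <- data.frame(gene = "ala1", anticodon = "UGC",
                      modification = "cmo5U", stringsAsFactors = FALSE)
    tab <- decodingTable(one, r)
    expect_length(tab, 61)
    hit <- names(tab)[lengths(tab) > 0]
    expect_setequal(hit, c("GCA", "GCC", "GCG", "GCU"))
    expect_false(any(c("UAA", "UAG", "UGA") %in% names(tab)))

    empty <- decodingTable(data.frame(gene = character(),
                                      anticodon = character()), r)
    expect_length(empty, 61)
    expect_true(all(lengths(empty) == 0))
})

test_that("every gene decodes its cognate codon unless position 34 is rewired", {
    reg <- loadRegistry("mg1655")
    r <- defaultWobbleRules()
    g <- genes(reg)
    for (i in seq_len(nrow(g))) {
        wc34 <- c(A = "U", C = "G", G = "C", U = "A")[
            substr(g$anticodon[i], 1, 1)]
        key <- if (nzchar(g$modification[i])) g$modification[i]
               else substr(g$anticodon[i], 1, 1)
        if (wc34 %in% rules(r)[[key]])
            expect_true(decodes(g[i, ], cognateCodon(g$anticodon[i]), r),
                        info = g$gene[i])
    }
    # lysidine is the rewired case: ileX must NOT read its naive cognate AUG
    ileX <- g[g$gene == "ileX", ]
    expect_false(decodes(ileX, cognateCodon(ileX$anticodon), r))
})

test_that("adding genes never removes a codon's decoder (monotonicity)", {
    r <- defaultWobbleRules()
    set.seed(42)
    bases <- c("A", "C", "G", "U")
    for (rep in 1:25) {
        n <- sample(3:10, 1)
        acs <- replicate(n, paste0(sample(bases, 3, replace = TRUE),
                                   collapse = ""))
        g <- data.frame(gene = sprintf("g%02d", seq_len(n)),
                        anticodon = acs, modification = "",
                        stringsAsFactors = FALSE)
        before <- decodingTable(g, r)
        extra <- data.frame(gene = "extra",
                            anticodon = paste0(sample(bases, 3, TRUE),
                                               collapse = ""),
                            modification = "", stringsAsFactors = FALSE)
        after <- decodingTable(rbind(g, extra), r)
        for (cod in names(before))
            expect_true(all(before[[cod]] %in% after[[cod]]))
    }
})

test_that("wobble rule config round-trips bit-identically", {
    shipped <- system.file("extdata", "wobble_rules.yaml",
                           package = "tRNAessentials")
    rs <- readWobbleRules(shipped)
    expect_identical(ruleVersion(rs), "mg1655-default-1")
    f <- tempfile(fileext = ".yaml")
    writeWobbleRules(rs, f)
    expect_identical(readLines(f), readLines(shipped))
    rs2 <- readWobbleRules(f)
    expect_identical(rules(rs2), rules(rs))
    # rule sets reject empty base sets and bad alphabets
    expect_error(wobbleRuleSet(list(G = character())), "nonempty")
    expect_error(wobbleRuleSet(list(G = "T")), "outside A/C/G/U")
})
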