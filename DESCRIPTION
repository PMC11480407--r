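Package: tRNAessentials
Title: Rule-Based Essentiality Screening of tRNA Transcription Units
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts which tRNA transcription units (TUs) of Escherichia
    coli K-12 MG1655 are essential from gene redundancy and codon-anticodon
    wobble decoding rules, and compares the predictions with an
    experimentally determined essentiality table for all 43 tRNA-containing
    TUs. Ships a curated registry of the 86 tRNA genes and their TU
    organisation, a configurable wobble rule engine, an in-silico TU
    deletion screen that names the essential tRNA elements and copy-number
    fractions, concordance reporting, differential-expression threshold
    calling with direction-resolved overlap between deletion strains,
    generic hypergeometric enrichment, and seeded simulators for registries
    with planted essential TUs and for differential-expression tables with
    known true effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'decoding.R'
    'dge.R'
    'registry.R'
    'essentiality.R'
    'validation.R'
    'pipeline.R'
    'synthetic.R'
    'tRNAessentials-package.R'
    'wobble-rules.R'
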