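---
title: "Predicting tRNA transcription-unit essentiality from wobble decoding rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting tRNA transcription-unit essentiality from wobble decoding rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tRNAessentials)
```

## The question

E. coli K-12 MG1655 carries 86 tRNA genes organised in 43 transcription
units (TUs) — single genes, tRNA-only operons, or mixed operons such as the
rRNA operons that carry spacer and trailer tRNAs. Because most anticodons
are encoded by several gene copies spread over several TUs, many TUs should
be individually dispensable: after deleting one TU, the remaining tRNAs may
still read every codon of the genetic code. A TU is predicted essential
precisely when its loss leaves some decoding demand with no remaining
supplier.

This package implements that prediction as a deterministic rule-based
screen, compares it with a packaged experimental outcome table for all 43
TUs, and post-processes differential-expression tables from deletion
strains.

## The model

**Demands.** Translation imposes 62 demands: each of the 61 sense codons
must be readable by at least one *elongator* tRNA, and initiation requires
at least one *initiator* (fMet) gene. The selenocysteine tRNA (selC), which
recodes a UGA stop in a context-dependent way, neither creates nor covers a
demand. Stop codons are never demands.

**Supply.** A tRNA gene reads a codon when codon positions 1 and 2 are
strict Watson–Crick complements of anticodon positions 36 and 35, and the
codon's third base is within reach of the anticodon's position 34 — the
wobble position. Position-34 reach depends on the base and its
modification, captured in a flat, editable rule table
(`defaultWobbleRules()`, shipped as YAML):

| key | reads codon-3 | rationale |
|-----|---------------|-----------|
| G | C, U | standard G:C plus G:U wobble |
| C | G | strict |
| A | U | strict (unmodified A34 is rare) |
| U (unmodified) | A, G | conservative split-box reading |
| cmo5U / mcmo5U | A, C, G, U | family-box "four-way" reading (Ala, Val, Pro, Thr, Ser, Leu-CUN isoacceptors) |
| mnm5U-type | A, G | split-box xm5(s2)U chemistry (Lys, Glu, Gln, Arg-UCU, Gly-UCC) |
| I (inosine) | A, C, G, U | see below |
| k2C (lysidine) | A | switches tRNA-Ile2 CAU from AUG to AUA |
| ac4C | G | restricts elongator tRNA-Met to AUG |
| Q (queuosine) | C, U | G34-derivative (Tyr, His, Asn, Asp) |

A gene's *effective wobble key* is its modification label when one is
annotated, otherwise its bare position-34 base.

**The screen.** `classifyTU()` deletes a TU in silico, recomputes the
codon→decoder table from the genes outside it, and collects the orphaned
demands. The TU is `predicted-essential` iff any demand is orphaned; the
*essential elements* are the genes inside the TU that serve an orphaned
demand, and the copy fractions report how many genome-wide copies of each
of the TU's isoacceptors the TU holds. `screenTUs()` applies this to all
TUs; everything is deterministic and all outputs are sorted.

## Design choices that were genuinely open

**Inosine reads all four bases here.** Classical wobble tables give
inosine (deaminated A34, Arg-ACG family) reach over A, C and U only. Under
that rule, deleting the argX-hisR-leuT-proM operon would orphan CGG (argX
is the only C34 Arg gene), adding argX itself to the operon's essential
elements. The curated essential-element annotation this package validates
against lists only hisR and proM for that operon, which entails that the
ArgQZYV inosine tRNAs retain (weak) reach over CGG; slow in-vivo reading
of CGG by ICG has indeed been reported. The default table therefore uses
I → {A, C, G, U}. The YAML rule file can be edited to restore the
three-base convention, and the screen will respond accordingly.

**leuZ carries no U34 modification label.** The Leu-UAA gene must read UUA
and UUG but not the Phe codons UUU/UUC; it therefore takes the bare-U
split-box rule {A, G}. The four-way cmo5U label is reserved for the
family-box isoacceptors where all four codons encode the same amino acid.

**Anticodon provenance.** The registry uses canonical MG1655 anticodons
(EcoCyc/GtRNAdb) throughout; in particular trpT is CCA (cognate UGG) and
cysT is GCA (cognate UGC/UGU), where some secondary descriptions disagree
with each other.

**Dosage is out of scope, deliberately.** The criterion is qualitative
demand coverage. Two experimentally essential TUs — ileX (an ileY copy
remains) and lysT-valT-lysW-valZ-lysYZQ (a single lysV and the valUXY
copies remain) — are predicted viable because a decoder copy survives;
their lethality is a copy-number/expression effect the coverage calculus
cannot see. The concordance report (`concordance()`) surfaces exactly these
two mismatches on the packaged tables; both are in the
predicted-viable/observed-essential direction, i.e. the screen makes no
false essential calls.

## The registry and outcome fixtures

`loadRegistry("mg1655")` loads the packaged 86-gene/43-TU table (TSV; one
row per gene with amino acid, anticodon 5'→3' in the RNA alphabet,
modification, functional class, TU membership). Loaders convert T→U and
record having done so. `loadOutcomes("mg1655")` loads the experimental
verdicts: 10 TUs deletable only with a complementing plasmid (essential),
33 deletable outright; annotations note the two TUs whose complementation
required the strong lpp promoter (argU, rrnC) and the three strongly
growth-impaired viable deletions (alaWX, valVW, metZWV). Outcomes are data,
not computations: the experimental definition (a TU that resists three
deletion attempts without complementation) is encoded as a boolean only.

```{r screen}
reg <- loadRegistry("mg1655")
scr <- screenTUs(reg)
scr
concordance(scr, loadOutcomes("mg1655", registry = reg))
```

## Differential expression after TU deletion

The second analysis stage post-processes per-gene differential-expression
tables from deletion strains (here ∆alaWX and ∆valVW, the two strains with
the strongest growth impairment in minimal medium). A gene is a DEG when
|log2FC| ≥ 1.5 (inclusive) and FDR < 0.05 (strict); `overlapDEGs()`
intersects two strains' call sets keeping per-strain directions, and
`summarizeOverlapByLabel()` buckets the common genes by ontology label.
The packaged worked-example tables carry the twelve genes called in both
strains — the fim operon genes and the fimZ regulator (pilus
assembly/protein folding, all up), four 23S rRNA genes (translation, all
up), and flgB/fliA (motility, down) — plus sub-threshold rows for the
remaining alanine/valine tRNA genes, whose published FDR bound (< 1e-4)
and direction are kept but whose exact values are synthetic stand-ins.

```{r dge}
a <- readDGETable("alaWX_example")
b <- readDGETable("valVW_example")
ov <- overlapDEGs(callDEGs(a), callDEGs(b))
ov
summarizeOverlapByLabel(ov, rbind(a, b))
```

Genome-wide DEG totals for the two strains are not recomputable from the
packaged tables (they require the raw sequencing data and the original
counting pipeline) and are deliberately not represented.
`hypergeomEnrichment()` provides the corresponding pathway-enrichment
operation (one-sided hypergeometric tail per pathway, BH across pathways)
as a generic tool; no pathway annotation ships with the package.

## Synthetic data: what it emulates and what it does not

`simulateRegistry()` builds random but viable registries: greedy coverage
(walk the sense codons in order, give each still-uncovered codon a strict
Watson–Crick decoder), redundancy per a small copy-number distribution
(default weights 0.5/0.3/0.2 for 1–3 copies, echoing the 1–7 copy range of
real isoacceptor families), two initiator genes, and a uniformly random TU
partition. Planting makes a TU essential by construction: all decoders of
a chosen codon move inside it. The returned ground truth is recomputed
from the finished registry by direct enumeration, so chance sole-decoder
placements are included. `simulateDGE()` emulates a per-gene DGE table:
a chosen fraction of genes gets a true effect (|log2FC| uniform on
[1.5, 3.5], random sign, measurement noise SD 0.1) and Beta(0.05, 1)
p-values; null genes get Normal(0, 0.5) log2FC and uniform p-values; FDR
is BH across all genes.

These generators reproduce the *combinatorial* structure of the registry
and the *threshold* behaviour of DEG calling. They do not simulate real
modification biology (simulated genes are unmodified), operon structure,
read counts, library-size effects or p-value dependence — so passing tests
demonstrate correctness of the screen and calling logic, not calibration
against real sequencing noise.

Both generators take an explicit seed, restore the caller's RNG state, and
are bit-reproducible for a fixed seed within this implementation.

## Numerical and procedural notes

* The screen, decoding tables and reports involve no randomness and no
  tolerances; all list outputs are sorted (gene name, codon, TU order of
  the registry) so reruns are byte-identical.
* BH adjustment is delegated to `stats::p.adjust`, hypergeometric tails to
  `stats::phyper`; the DEG thresholds are inclusive at the log2FC bound
  and strict at the FDR bound.
* Registry validation treats an anticodon/amino-acid mismatch under the
  genetic code as a warning, not an error, except that lysidine-modified
  CAU annotated as Ile is recognised as consistent (the modification is
  precisely what recodes it).
* Test problem sizes: the brute-force oracle cross-check runs on the full
  fixture and on 100 simulated registries of ~70 genes in 6 TUs; the
  null-FDR audit uses 200 replicates of 400 genes. These sizes give
  sub-minute suites while leaving Monte-Carlo error well below the margins
  asserted.

## Known limitations

* Essentiality is demand coverage only; dosage effects (the two known
  mismatches) are documented, not modelled.
* The wobble table is global: reach is a property of the position-34 key
  alone, not of the codon box context. The leuZ/inosine choices above are
  the two places where this simplification had to be resolved by hand.
* Growth-impairment phenotypes of viable deletions are carried as
  annotations only; predicting impairment is out of scope.
* The registry has no genomic coordinates, promoters or secondary
  structure; TU identity is the only positional information.
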