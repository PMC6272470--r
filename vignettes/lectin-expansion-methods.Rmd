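---
title: "Methods: quantifying lectin gene-family expansion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying lectin gene-family expansion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lectinscape)
```

## The problem

Plant lectins — proteins with at least one non-catalytic carbohydrate
recognition domain (CRD) — fall into twelve evolutionarily unrelated
families (ABA, amaranthin, CRA, cyanovirin, EUL, GNA, hevein, jacalin,
legume, LysM, Nictaba, ricin B). In a paleopolyploid genome such as
soybean's, family sizes range from zero to well over a hundred genes, and
the expansion is driven by a mixture of tandem duplication (local copies
within a chromosomal neighbourhood) and segmental duplication (copies
carried along with a duplicated chromosomal segment). `lectinscape`
quantifies that mixture from four standard annotation inputs: a GFF3 gene
annotation, an InterProScan-style domain-hit table, a signal-peptide /
transmembrane topology table, and an MCScanX-style collinearity file with
per-pair Ks (synonymous substitution rate) values.

## Family classification and domain architectures

A gene belongs to family *F* when at least one of its domain hits carries
an accession assigned to *F* in the family-definition config
(`lectin_family_definitions()`). The packaged config uses Pfam accessions
where the CRD has one; the EUL, Nictaba and CRA domains have no Pfam entry
and are represented by synthetic placeholder accessions that an
alignment-derived hit table is expected to use.

Two decisions here were genuinely open:

* **Multi-family genes.** Published per-family counts are additive (they
  sum to the total), which is only possible if each gene is counted once.
  The default therefore assigns a multi-family gene to the family of its
  best-scoring lectin hit and warns; `multi_family = "strict"` counts it
  in every family and knowingly breaks additivity.
* **Truncation.** Truncated CRDs (observed in the GNA family at 64–111 aa
  against a ~110 aa domain) are flagged when the observed hit length is
  strictly below `truncation_fraction` (default 0.75) of the family's
  reference length. The published account gives no rule, so the fraction
  is a config knob; the strict inequality makes the boundary case
  deterministic.

The canonical architecture string joins tokens in N-to-C order with `|`:
`SP` first when a signal peptide is predicted, lectin domains as their
family label, other domains through a controlled accession-to-token
vocabulary (kinase, S-locus glycoprotein, PAN, F-box, GH5/18/19/27, ...),
and `TM` tokens interleaved at their amino-acid position. Overlapping hits
of the same accession are merged; overlapping hits of different accessions
are both kept, ordered by start then accession, so the string is a pure
function of the hit table. Architecture groups (the receptor-kinase
layouts, F-box lectins, glycoside-hydrolase fusions, tandem-arrayed lectin
units) are then exact-string tallies, so two genes fall in one group iff
their token sequences are identical.

N-terminal transmembrane predictions that lie entirely within the first
30 aa of a protein that also has a signal peptide are discarded when the
topology table is read: the SP's hydrophobic core is routinely re-reported
as a spurious TM segment, and 30 aa covers typical plant signal peptides.

## The tandem rule

Gene order is the 0-based rank of each gene within its chromosome, sorted
by the smaller genomic coordinate (ties broken by end, then id, so ranks
never depend on input row order; a strand-aware TSS ordering is available
as `order_by = "tss"`). Two genes with ranks $r_1 < r_2$ have
$r_2 - r_1 - 1$ intervening genes, counted over the *entire* annotation,
not just lectin genes — "intervening genes" reads most naturally as the
physical gene neighbourhood (a lectin-only counting is exposed as
`intervening = "lectin"`).

A tandem cluster is a maximal chain of genes that share a family and a
chromosome with at most `max_intervening` (default 10) intervening genes
between *consecutive* members. Chaining is transitive, so a cluster's
end-to-end span may exceed the window. The boundary is inclusive: 10
intervening genes link, 11 do not. Genes on unmapped scaffolds are kept in
family totals but can never join a cluster (they have no meaningful
neighbourhood) and are absent from chromosome maps.

Correctness is checked against an independent brute-force oracle —
enumerate every same-family pair within the window, then take connected
components — on random chromosomes up to 1,000 genes.

## The Ks filter and segmental assignment

Collinear blocks are consumed, not computed: the reader parses the
MCScanX-style dialect (block headers `## Alignment <id>: ...`, one pair
per line, Ks as the last field) with block-scoped, orientation-free pair
identity. Pairs with Ks strictly above `ks_max = 1.0` are excluded —
beyond Ks ≈ 1 synonymous sites are saturated and the estimate is
unreliable — so a pair at exactly 1.0 is retained. Pairs with missing Ks
are excluded conservatively with their own reason code. A lectin gene is
segmentally duplicated when it occurs at either end of at least one
retained pair (a block need only contain *one* lectin gene), and genes
whose every pair fails the filter are reported separately so the cost of
the saturation filter is visible.

## Mechanism attribution

With the tandem gene set $T$ and segmental gene set $S$ over the lectin
universe $U$ (including unplaced genes, which can be segmental but not
tandem), each gene gets exactly one label: `both` $= T \cap S$,
`tandem_only` $= T \setminus S$, `segmental_only` $= S \setminus T$,
`other` $= U \setminus (T \cup S)$. The residual class is never
interpreted positively — retrotransposition or transposed duplication
would need evidence this pipeline does not consume. Percentages are over
$|U|$; pre-rounding counts always sum to $|U|$ exactly.

All printed percentages in the package use rounding half away from zero to
one decimal (`round_half_up()`): base R's half-to-even rounding fails to
reproduce standard printed tables (e.g. 6/359 must print 1.7, 3/359 must
print 0.8).

## The synthetic genome

`simulate_genome()` exists so every stage can be validated against planted
truth without any external download. It emulates:

* a background annotation (default 5 chromosomes × 400 genes, intergenic
  gaps 2–20 kb) plus a couple of lectin genes on unmapped scaffolds;
* planted tandem arrays (default 12, 2–6 members, 0–8 intervening genes)
  and scattered lectin genes (default 60), with families drawn from the
  observed soybean proportions (GNA ≈ 46%, legume ≈ 26%, LysM ≈ 13%, ...);
* collinear blocks (default 30 — about one block per three lectin genes,
  the density seen in the soybean survey's 121 blocks for 359 genes) of
  3–8 consecutive gene pairs, preferentially anchored on lectin genes;
* per-pair Ks from a two-component lognormal mixture: a recent component
  truncated to Ks ≤ `ks_max` and an ancient one truncated to
  Ks > `ks_max`, the ancient component chosen with probability
  `fraction_ks_above_threshold` (default 0.16, matching a survey in which
  32 of ~198 collinear duplicates were lost to saturation). Truncating
  each component at the threshold makes the planted saturated fraction
  exactly binomial and the truth labels unambiguous;
* per-protein domain hits and SP/TM annotations generated from the
  family's architecture templates, so the classifier must reconstruct the
  planted architecture string exactly.

Two generator constraints make truth labels well defined rather than
merely probable: scattered lectin genes and distinct same-family arrays
are placed with a same-family rank separation wider than the tandem
window, so the planted arrays are *exactly* the clusters the rule can
detect; and segmental truth is the planted pair list itself after the Ks
cut. On such data, label recovery must be 100% when detection parameters
equal generation parameters — any discrepancy is a defect, not noise.

What the simulator does **not** emulate: real sequence evolution (domain
hits are laid out geometrically, not aligned), isoforms (one protein per
gene), whole-genome-duplication block structure, gene loss inside arrays,
or annotation noise beyond what the I/O tests inject. Passing on synthetic
data therefore demonstrates the *rules* are implemented correctly, not
that any biological conclusion transfers to a particular assembly.

## Maximum parsimony

The phylogenetic module is deliberately small and exact. `fitch_score()`
implements Fitch small parsimony over per-site state sets encoded as
bitmasks; gaps are a 21st character state by default (`gap_as_state =
FALSE` treats them as missing). The score is invariant under re-rooting
and leaf permutation, which the tests assert.

`branch_and_bound_search()` performs stepwise taxon addition in input
order; a partial tree is pruned when its Fitch score plus a per-site lower
bound — one change for every state present among unadded taxa but absent
from the partial tree at that site — exceeds the best complete score.
Ties are kept, so the result is the *complete* set of optimal topologies,
returned in canonical newick order (rooted for display at the
lexicographically smallest taxon, children sorted by smallest descendant).
The search refuses more than 15 taxa: with $(2n-5)!!$ topologies an exact
search beyond that is the wrong tool. Exactness is verified against full
enumeration (score *and* tree set) for all test matrices with ≤ 7 taxa.

`is_monophyletic()` asks whether any edge bipartition separates exactly
the query taxa — on data with two deeply divergent planted clades (an
EUL-like triplet against a ricin-B-like set), every optimal tree must
separate the triplet, which is the property-level analogue of showing that
two lectin families that share a structural fold are nonetheless distinct
clades.

## Problem sizes and numerical choices

The test suite and acceptance script run at sizes chosen to exercise every
rule without waste: random tandem instances of 50–1,000 genes (100
instances in the acceptance property), simulated genomes of ~2,000 genes
with ~105 lectin genes, parsimony matrices of 4–8 taxa and 10–60 sites.
Degenerate inputs are defined, not special-cased: empty family universes
warn and report 0.0, empty cluster sets summarise to zeros, empty pair
sets give empty segmental assignments, and a zero-structure simulation
labels every gene `other`.

## Known limitations

* Family definitions ship placeholder accessions for the three CRDs
  without Pfam entries; real analyses must supply the accessions their
  hit-generation pipeline emits.
* The collinearity reader targets one (configurable-by-convention) MCScanX
  dialect; exotic dialect variants need pre-conversion.
* Per-family segmental tallies count a gene once per family, so with
  multi-family genes in strict mode the per-family table is not additive —
  the distinct-gene total is reported alongside for that reason.
* The parsimony module is topological: no branch lengths, no bootstrap,
  no likelihood.
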