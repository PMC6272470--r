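# lectinscape

Gene-family expansion analysis for plant lectins.

Plant lectins — proteins carrying one or more non-catalytic carbohydrate
recognition domains (CRDs) — form twelve unrelated families whose sizes
vary wildly within a single genome. `lectinscape` is for researchers who
have standard annotation products in hand (a GFF3 gene annotation, an
InterProScan-style domain-hit table, SignalP/TMHMM-style topology calls,
and an MCScanX-style collinearity file with per-pair Ks values) and want a
reproducible, tested answer to: *which lectin families does this genome
carry, what are their domain architectures, and how much of each family's
expansion is due to tandem versus segmental duplication?*

## The method

1. **Classification.** A gene joins family *F* iff it has a domain hit
   whose accession is assigned to *F*; its canonical architecture string
   (e.g. `SP|GNA|Slocus|PAN|TM|kinase` for a G-type lectin receptor
   kinase) is built from hits, signal peptide and TM segments in N→C
   order.
2. **Tandem duplication.** With genes ranked by start position within
   each chromosome, a tandem cluster is a maximal transitive chain of
   same-family, same-chromosome genes with ≤ *k* intervening genes
   (default *k* = 10) between consecutive members; the count r₂ − r₁ − 1
   runs over all annotated genes.
3. **Segmental duplication.** Collinear gene pairs are filtered at
   Ks ≤ 1.0 (synonymous sites saturate above that; Ks exactly 1.0 is
   retained, missing Ks is excluded); a lectin gene is segmental when it
   occurs at either end of a retained pair.
4. **Attribution.** Every lectin gene gets exactly one label —
   `tandem_only`, `segmental_only`, `both` (= T ∩ S), or `other` — with
   per-family and overall percentage tables.
5. **Parsimony.** A small exact maximum-parsimony module (Fitch scoring,
   max-mini branch-and-bound, ≤ 15 taxa) supports family-monophyly
   checks, e.g. that an EUL-homolog triplet forms a clade apart from
   ricin B homologs.

A synthetic-genome simulator (`simulate_genome()`) plants labelled tandem
arrays, collinear blocks and a recent/ancient Ks mixture, so the whole
pipeline is validated against known truth — label recovery on planted
data is exact, not approximate.

## Worked example

```r
library(lectinscape)

cfg <- simulation_config(seed = 42)
sim <- simulate_genome(cfg)
paths <- write_simulation(sim, file.path(tempdir(), "demo"))

genes  <- read_gene_annotation(paths[["gff3"]])
hits   <- read_domain_table(paths[["domains"]])
topo   <- read_topology_table(paths[["topology"]])
pairs  <- read_collinearity(paths[["collinearity"]])

asg      <- assign_families(hits, lectin_family_definitions(), topology = topo)
clusters <- detect_tandem_clusters(genes, asg, max_intervening = 10)
seg      <- assign_segmental(filter_pairs_by_ks(pairs, ks_max = 1.0), asg$gene_id)
part     <- attribute_mechanisms(unique(unlist(clusters$members)),
                                 seg$segmental_genes, asg$gene_id)

summarize_families(asg, genes = genes)
#> # A tibble: 12 × 4
#>    family     n_genes percentage chromosomes
#>  1 ABA              0        0   /
#>  ...
#>  6 GNA             46       40.4 1, 2, 3, 4, 5
#>  9 legume          35       30.7 1, 2, 3, 4, 5
#> 10 LysM            14       12.3 1, 3, 4, 5
#>  ...

part$summary
#> # A tibble: 4 × 3
#>   mechanism      n_genes percentage
#> 1 tandem_only         42       36.8
#> 2 segmental_only      17       14.9
#> 3 both                10        8.8
#> 4 other               45       39.5

head(group_architectures(asg), 3)
#> # A tibble: 3 × 2
#>   architecture                n_genes
#> 1 SP|legume|TM|kinase              16
#> 2 SP|thaumatin|GNA|TM|kinase       14
#> 3 SP|GNA|Slocus|PAN|TM|kinase      10
```

The family summary reads as a per-family census (counts, share of all
lectin genes, chromosome localisation, with `"all except chr N"` used for
near-complete occupancy). The mechanism summary says how much of the
lectin complement each duplication route explains — here 36.8% of the
simulated lectin genes sit in tandem clusters only, 14.9% only in
retained collinear pairs, 8.8% in both, and the rest in neither. The
architecture groups are exact-string tallies of the chimerolectin
layouts, dominated here by lectin receptor-like kinases.

For published-survey arithmetic, `table1_fixture()` and
`table3_fixture()` carry the soybean per-family census (359 genes, nine
non-empty families) and its duplication summary (53 tandem clusters, 188
tandem genes); `summarize_families(table1_fixture()[, c("family",
"n_genes")])` reproduces every printed percentage under half-up rounding.

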