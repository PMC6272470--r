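Package: lectinscape
Title: Gene-Family Expansion Analysis for Plant Lectins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies genes into plant lectin families from protein domain
    hits, builds canonical domain-architecture strings with signal-peptide and
    transmembrane annotations, and quantifies gene-family expansion by tandem
    and segmental duplication. Tandem clusters are detected with a
    same-family / same-chromosome / bounded-intervening-gene rule; segmental
    duplicates are assigned from collinear gene blocks after filtering pairs
    by synonymous substitution rate (Ks), and every lectin gene is attributed
    to a duplication mechanism (tandem only, segmental only, both, or other).
    Includes a synthetic-genome simulator with planted, labelled duplication
    structure for end-to-end validation, and a small exact maximum-parsimony
    module (Fitch scoring with branch-and-bound search) for family-monophyly
    checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    purrr,
    readr,
    rlang,
    seqinr,
    stringr,
    tibble,
    tidyr,
    yaml,
    stats,
    utils
Suggests:
    igraph,
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
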