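defs <- lectin_family_definitions()

hit_row <- function(id, acc, s, e, score = 1e-30, desc = "d") {
  tibble::tibble(protein_id = id, domain_accession = acc, description = desc,
                 d_start = as.integer(s), d_end = as.integer(e), score = score)
}

test_that("a single lectin hit assigns exactly one family", {
  hits <- hit_row("G1", "PF01476", 10, 50)
  asg <- assign_families(hits, defs)
  expect_equal(asg$family, "LysM")
  expect_equal(asg$families, "LysM")
  expect_false(asg$multi_family)
})

test_that("chimerolectins combine lectin and enzymatic domains in order", {
  hits <- dplyr::bind_rows(
    hit_row("G1", "PF00187", 35, 74),          # hevein domain
    hit_row("G1", "PF00182", 100, 329)         # GH19 chitinase
  )
  topo <- tibble::tibble(protein_id = "G1", has_signal_peptide = TRUE,
                         tm_segments = list(matrix(integer(0), ncol = 2)))
  asg <- assign_families(hits, defs, topology = topo)
  expect_equal(asg$family, "hevein")
  expect_equal(asg$architecture, "SP|hevein|chitinase")
})

test_that("tandem-arrayed lectin units and receptor-kinase layouts tokenize", {
  jac <- dplyr::bind_rows(
    hit_row("J1", "PF01419", 1, 135),
    hit_row("J1", "PF01419", 150, 284),
    hit_row("J1", "PF01419", 300, 434)
  )
  expect_equal(architecture_string(build_architecture(jac, defs)),
               "jacalin|jacalin|jacalin")
  leg <- dplyr::bind_rows(
    hit_row("L1", "PF00139", 31, 260),
    hit_row("L1", "PF00069", 310, 559)
  )
  tm <- matrix(c(280L, 300L), ncol = 2)
  expect_equal(
    architecture_string(build_architecture(leg, defs, has_signal_peptide = TRUE,
                                           tm_segments = tm)),
    "SP|legume|TM|kinase"
  )
  expect_length(build_architecture(jac[0, ], defs), 0L)
})

test_that("genes without a lectin domain are excluded entirely", {
  hits <- dplyr::bind_rows(
    hit_row("G1", "PF00069", 10, 260),     # kinase only
    hit_row("G2", "PF01453", 10, 119)      # GNA
  )
  asg <- assign_families(hits, defs)
  expect_equal(asg$gene_id, "G2")
})

test_that("overlapping same-accession hits merge; different accessions both kept", {
  hits <- dplyr::bind_rows(
    hit_row("G1", "PF01453", 10, 80),
    hit_row("G1", "PF01453", 60, 119),     # overlaps, same accession
    hit_row("G1", "PF00954", 70, 180)      # overlaps, different accession
  )
  expect_equal(architecture_string(build_architecture(hits, defs)), "GNA|Slocus")
})

test_that("truncation flagging is a strict less-than on the scaled reference", {
  expect_true(flag_truncated(80, 110, 0.9))
  expect_false(flag_truncated(82.5, 110, 0.75))   # exactly at threshold
  set.seed(13)
  lens <- sample(10:200, 1000, replace = TRUE)
  expect_identical(flag_truncated(lens, 110, 0.75), lens < 0.75 * 110)
})

test_that("multi-family genes default to their best-scoring family with a warning", {
  hits <- dplyr::bind_rows(
    hit_row("G1", "PF01453", 10, 119, score = 1e-20),   # GNA, weaker
    hit_row("G1", "PF00139", 150, 379, score = 1e-45)   # legume, stronger
  )
  expect_warning(asg <- assign_families(hits, defs), "more than one")
  expect_equal(asg$family, "legume")
  expect_true(asg$multi_family)
  expect_equal(asg$families, "GNA,legume")
  strict <- suppressWarnings(assign_families(hits, defs, multi_family = "strict"))
  expect_setequal(strict$family, c("GNA", "legume"))
  expect_equal(nrow(strict), 2L)
})

test_that("family assignment is invariant to hit row order", {
  set.seed(29)
  accs <- c("PF01453", "PF00139", "PF01476", "PF01419", "PF00069", "PF00646")
  hits <- dplyr::bind_rows(lapply(1:300, function(i) {
    s <- sample(500, 1)
    hit_row(sprintf("G%03d", sample(80, 1)), sample(accs, 1), s, s + 99,
            score = 10^-runif(1, 10, 50))
  }))
  a1 <- suppressWarnings(assign_families(hits, defs))
  a2 <- suppressWarnings(assign_families(hits[sample(nrow(hits)), ], defs))
  expect_equal(a1, a2)
  # per-family counts equal a brute-force membership scan over the hit table
  acc2fam <- c(PF01453 = "GNA", PF00139 = "legume", PF01476 = "LysM",
               PF01419 = "jacalin")
  for (fam in unique(a1$family)) {
    ids <- unique(hits$protein_id[!is.na(acc2fam[hits$domain_accession]) &
                                    acc2fam[hits$domain_accession] == fam])
    # brute-force count of genes whose best lectin hit is in fam
    best <- vapply(ids, function(id) {
      lh <- hits[hits$protein_id == id &
                   hits$domain_accession %in% names(acc2fam), ]
      unname(acc2fam[lh$domain_accession[which.min(lh$score)]])
    }, character(1))
    expect_equal(sum(a1$family == fam), sum(best == fam))
  }
})

test_that("an accession claimed by two families is a definition error", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("families:",
               "  GNA: {accessions: [PF01453], reference_domain_length: 110, truncation_fraction: 0.75}",
               "  legume: {accessions: [PF01453], reference_domain_length: 230, truncation_fraction: 0.75}",
               "tokens:",
               "  PF00069: {token: kinase, length: 250}"), path)
  expect_error(lectin_family_definitions(path), "two families")
})

test_that("architecture strings round-trip through tokenization", {
  for (tokens in list(character(0), "EUL", c("SP", "GNA", "TM", "kinase"),
                      c("F-box", "Nictaba"), c("jacalin", "jacalin"))) {
    expect_identical(parse_architecture(architecture_string(tokens)), tokens)
  }
})

test_that("architecture grouping counts exact strings, sorted by frequency", {
  asg <- tibble::tibble(
    gene_id = c("a", "b", "c"),
    architecture = c("SP|GNA|TM|kinase", "SP|GNA|TM|kinase", "SP|GNA")
  )
  grp <- group_architectures(asg)
  expect_equal(grp$architecture, c("SP|GNA|TM|kinase", "SP|GNA"))
  expect_equal(grp$n_genes, c(2L, 1L))
  expect_equal(nrow(group_architectures(asg[0, ])), 0L)
})

test_that("simulated genomes recover planted families and architectures exactly", {
  cfg <- simulation_config(seed = 47, n_chromosomes = 3, genes_per_chromosome = 200,
                           n_tandem_arrays = 5, n_scattered_lectins = 30,
                           n_collinear_blocks = 8)
  sim <- simulate_genome(cfg)
  d <- withr::local_tempdir()
  paths <- write_simulation(sim, d)
  hits <- read_domain_table(paths[["domains"]])
  topo <- read_topology_table(paths[["topology"]])
  asg <- assign_families(hits, defs, topology = topo)
  m <- merge(asg, sim$truth$genes, by = "gene_id")
  expect_equal(nrow(m), nrow(sim$truth$genes))
  expect_identical(m$family.x, m$family.y)
  expect_identical(m$architecture.x, m$architecture.y)
  # grouped architecture counts equal the planted template tallies
  planted <- table(sim$truth$genes$architecture)
  grp <- group_architectures(asg)
  expect_equal(stats::setNames(grp$n_genes, grp$architecture)[names(planted)],
               stats::setNames(as.integer(planted), names(planted)))
})
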