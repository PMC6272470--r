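# two-gene family at given ranks on a 30-gene chromosome
two_gene_case <- function(r1, r2) {
  genes <- assign_gene_ranks(make_genes("chr1", 30))
  ordered <- genes$gene_id[order(genes$rank)]
  asg <- tibble::tibble(gene_id = ordered[c(r1, r2) + 1L], family = "GNA")
  list(genes = genes, assignments = asg)
}

test_that("the intervening-gene window is inclusive at the boundary", {
  at10 <- two_gene_case(5L, 16L)    # 10 intervening genes
  cl <- detect_tandem_clusters(at10$genes, at10$assignments, max_intervening = 10)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_members, 2L)
  expect_equal(cl$gaps[[1]], 10L)
  at11 <- two_gene_case(5L, 17L)    # 11 intervening genes
  expect_equal(nrow(detect_tandem_clusters(at11$genes, at11$assignments)), 0L)
})

test_that("chaining is transitive beyond the pairwise window", {
  genes <- assign_gene_ranks(make_genes("chr1", 40))
  ordered <- genes$gene_id[order(genes$rank)]
  # ranks 0, 11, 22: consecutive gaps of 10, end-to-end gap of 21
  asg <- tibble::tibble(gene_id = ordered[c(1L, 12L, 23L)], family = "legume")
  cl <- detect_tandem_clusters(genes, asg)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_members, 3L)
})

test_that("clusters never mix families, chromosomes, or unplaced genes", {
  genes <- assign_gene_ranks(dplyr::bind_rows(
    make_genes("chr1", 10), make_genes("chr2", 10), make_genes("scaffold_1", 4)
  ))
  asg <- tibble::tibble(
    gene_id = c("chr1_g001", "chr1_g002",      # same family, adjacent
                "chr1_g003", "chr2_g001",      # same family, different chromosome
                "scaffold_1_g001", "scaffold_1_g002"),  # unplaced pair
    family = c("GNA", "GNA", "legume", "legume", "LysM", "LysM")
  )
  cl <- detect_tandem_clusters(genes, asg)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$family, "GNA")
})

test_that("negative windows are rejected", {
  case <- two_gene_case(0L, 1L)
  expect_error(detect_tandem_clusters(case$genes, case$assignments,
                                      max_intervening = -1), "max_intervening")
})

test_that("detector matches the pairwise-link + components oracle", {
  set.seed(53)
  for (rep in 1:15) {
    inst <- random_tandem_instance(sample(100:600, 1), sample(5:60, 1))
    k <- sample(c(0L, 1L, 5L, 10L), 1)
    cl <- detect_tandem_clusters(inst$genes, inst$assignments, max_intervening = k)
    expect_identical(cluster_key(cl), oracle_tandem(inst$genes, inst$assignments, k))
  }
})

test_that("the cluster set grows monotonically with the window", {
  set.seed(59)
  inst <- random_tandem_instance(400, 50)
  prev <- detect_tandem_clusters(inst$genes, inst$assignments, max_intervening = 0)
  for (k in c(2L, 5L, 10L, 20L)) {
    cur <- detect_tandem_clusters(inst$genes, inst$assignments, max_intervening = k)
    cur_sets <- lapply(cur$members, identity)
    for (m in prev$members) {
      expect_true(any(vapply(cur_sets, function(s) all(m %in% s), logical(1))))
    }
    prev <- cur
  }
})

test_that("output is invariant under gene-id relabeling", {
  set.seed(61)
  inst <- random_tandem_instance(200, 30)
  relabel <- stats::setNames(sprintf("Z%03d", seq_len(nrow(inst$genes))),
                             inst$genes$gene_id)
  genes2 <- inst$genes
  genes2$gene_id <- unname(relabel[genes2$gene_id])
  asg2 <- inst$assignments
  asg2$gene_id <- unname(relabel[asg2$gene_id])
  cl1 <- detect_tandem_clusters(inst$genes, inst$assignments)
  cl2 <- detect_tandem_clusters(genes2, asg2)
  key1 <- cluster_key(cl1)
  key2 <- sort(vapply(cl2$members, function(m) {
    paste(sort(names(relabel)[match(m, relabel)]), collapse = ",")
  }, character(1)), method = "radix")
  expect_identical(key1, key2)
})

test_that("lectin-only intervening counting is a stricter neighbourhood", {
  genes <- assign_gene_ranks(make_genes("chr1", 40))
  ordered <- genes$gene_id[order(genes$rank)]
  # two GNA genes 12 background genes apart, with a lectin of another family between
  asg <- tibble::tibble(gene_id = ordered[c(1L, 8L, 15L)],
                        family = c("GNA", "legume", "GNA"))
  expect_equal(nrow(detect_tandem_clusters(genes, asg, max_intervening = 1)), 0L)
  cl <- detect_tandem_clusters(genes, asg, max_intervening = 1,
                               intervening = "lectin")
  expect_equal(nrow(cl), 1L)   # only the legume gene lies between them
})

test_that("tandem summary tallies clusters and distinct genes with totals", {
  sim <- simulate_genome(simulation_config(seed = 67))
  d <- withr::local_tempdir()
  paths <- write_simulation(sim, d)
  genes <- read_gene_annotation(paths[["gff3"]])
  asg <- tibble::tibble(gene_id = sim$truth$genes$gene_id,
                        family = sim$truth$genes$family)
  cl <- detect_tandem_clusters(genes, asg)
  smry <- summarize_tandem(cl, asg)
  planted <- sim$truth$arrays
  expect_equal(smry$n_clusters[smry$family == "total"], nrow(planted))
  expect_equal(smry$n_genes_involved[smry$family == "total"],
               length(unique(unlist(planted$members))))
  for (fam in setdiff(smry$family, "total")) {
    pf <- planted[planted$family == fam, ]
    expect_equal(smry$n_clusters[smry$family == fam], nrow(pf))
    expect_equal(smry$n_genes_involved[smry$family == fam],
                 length(unique(unlist(pf$members))))
  }
  expect_true(sum(cl$n_members) >= 2L * nrow(cl))
  none <- summarize_tandem(cl[0, ], asg)
  expect_true(all(none$n_clusters == 0L))
})
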