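# Independent oracles and small fixture builders shared across tests.

# gene table from explicit per-chromosome layouts; start = (slot + 1) * 1000
make_genes <- function(chrom, n, prefix = chrom) {
  tibble::tibble(
    gene_id = sprintf("%s_g%03d", prefix, seq_len(n)),
    chromosome = chrom,
    start = seq_len(n) * 1000L,
    end = seq_len(n) * 1000L + 500L,
    strand = "+"
  )
}

# brute-force tandem oracle: link every pair of placed lectin genes that is
# same-family, same-chromosome and within the rank window, then take
# connected components with >= 2 members (igraph)
oracle_tandem <- function(genes, assignments, max_intervening = 10L) {
  lect <- merge(assignments[, c("gene_id", "family")],
                genes[, c("gene_id", "chromosome", "rank", "is_placed")],
                by = "gene_id")
  lect <- lect[lect$is_placed, , drop = FALSE]
  if (nrow(lect) < 2L) return(character(0))
  edges <- character(0)
  for (i in seq_len(nrow(lect) - 1L)) {
    for (j in seq(i + 1L, nrow(lect))) {
      if (lect$family[i] == lect$family[j] &&
          lect$chromosome[i] == lect$chromosome[j] &&
          abs(lect$rank[i] - lect$rank[j]) - 1L <= max_intervening) {
        edges <- c(edges, lect$gene_id[i], lect$gene_id[j])
      }
    }
  }
  if (length(edges) == 0L) return(character(0))
  g <- igraph::make_graph(edges, directed = FALSE)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  members <- members[lengths(members) >= 2L]
  unname(sort(vapply(members, function(m) paste(sort(m), collapse = ","),
                     character(1)), method = "radix"))
}

# canonical form of a detector's cluster set for comparison with the oracle
cluster_key <- function(clusters) {
  if (nrow(clusters) == 0L) return(character(0))
  sort(vapply(clusters$members, function(m) paste(sort(m), collapse = ","),
              character(1)), method = "radix")
}

# random tandem test instance: one chromosome, random lectin subset/families
random_tandem_instance <- function(n_genes, n_lectin, families = c("GNA", "legume", "LysM")) {
  genes <- make_genes("chr1", n_genes)
  genes <- assign_gene_ranks(genes)
  lect_idx <- sort(sample(n_genes, n_lectin))
  assignments <- tibble::tibble(
    gene_id = genes$gene_id[order(genes$start)][lect_idx],
    family = sample(families, n_lectin, replace = TRUE)
  )
  list(genes = genes, assignments = assignments)
}

# integer-arithmetic percentage oracle: round(100 * n / total, 1) half-up,
# computed with exact integer operations only
oracle_percentage <- function(n, total) {
  if (total == 0L) return(0)
  num <- 1000L * as.integer(n)
  q <- num %/% total
  r <- num %% total
  (q + as.integer(2L * r >= total)) / 10
}

# monophyly oracle: root at a tip outside the subset and compare the MRCA
# clade with the subset
oracle_monophyletic <- function(tree, subset) {
  if (length(subset) == 1L) return(TRUE)
  out <- setdiff(tree$tip.label, subset)[1]
  rooted <- ape::root(tree, outgroup = out, resolve.root = TRUE)
  mrca <- ape::getMRCA(rooted, subset)
  clade <- ape::extract.clade(rooted, mrca)$tip.label
  setequal(clade, subset)
}

# random aligned character matrix over a small amino-acid alphabet
random_matrix <- function(n_taxa, n_sites, alphabet = c("A", "C", "D", "E", "F", "G", "-")) {
  m <- matrix(sample(alphabet, n_taxa * n_sites, replace = TRUE), nrow = n_taxa,
              dimnames = list(paste0("t", seq_len(n_taxa)), NULL))
  character_matrix(m)
}

# two divergent planted clades: descendants of two unrelated ancestor
# sequences with light within-clade mutation
planted_clade_matrix <- function(n_a = 3L, n_b = 4L, n_sites = 60L, mut = 0.05) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L")
  anc_a <- sample(aa, n_sites, replace = TRUE)
  anc_b <- sample(aa, n_sites, replace = TRUE)
  mutate_seq <- function(anc) {
    hit <- stats::runif(n_sites) < mut
    anc[hit] <- sample(aa, sum(hit), replace = TRUE)
    anc
  }
  rows <- c(
    lapply(seq_len(n_a), function(i) mutate_seq(anc_a)),
    lapply(seq_len(n_b), function(i) mutate_seq(anc_b))
  )
  m <- do.call(rbind, rows)
  rownames(m) <- c(paste0("eul_", seq_len(n_a)), paste0("ricb_", seq_len(n_b)))
  character_matrix(m)
}

# exhaustive parsimony oracle via phangorn: score every unrooted topology
oracle_exhaustive_parsimony <- function(mat) {
  taxa <- rownames(mat)
  all_t <- phangorn::allTrees(length(taxa), rooted = FALSE, tip.label = taxa)
  pd <- phangorn::phyDat(unclass(mat), type = "USER",
                         levels = sort(unique(as.vector(mat))))
  sc <- vapply(all_t, function(t) phangorn::parsimony(t, pd, method = "fitch"),
               numeric(1))
  list(score = min(sc), trees = all_t[sc == min(sc)])
}

# TRUE iff two multiPhylo sets contain the same unrooted topologies
same_tree_set <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  all(vapply(a, function(x) {
    any(vapply(b, function(y) phangorn::RF.dist(x, y) == 0, logical(1)))
  }, logical(1)))
}
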