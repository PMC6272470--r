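#' Attribute each lectin gene to a duplication mechanism
#'
#' Partitions the lectin gene universe into four disjoint, exhaustive
#' classes: `tandem_only` (in a tandem cluster, in no retained collinear
#' pair), `segmental_only`, `both`, and `other` (neither; residual
#' mechanisms such as retrotransposition are never inferred positively).
#' Percentages are over the full universe, including unplaced genes (which
#' can be segmental but never tandem), rounded half-up to one decimal.
#'
#' @param tandem_genes character vector of genes in tandem clusters.
#' @param segmental_genes character vector of segmentally duplicated genes.
#' @param universe character vector of all lectin gene ids; both input sets
#'   must be subsets of it.
#' @return list of class `mechanism_partition`: `labels` (tibble `gene_id`,
#'   `mechanism`), `summary` (tibble `mechanism`, `n_genes`, `percentage`
#'   in the fixed order tandem_only, segmental_only, both, other).
#' @export
attribute_mechanisms <- function(tandem_genes, segmental_genes, universe) {
  universe <- unique(universe)
  stray <- setdiff(c(tandem_genes, segmental_genes), universe)
  if (length(stray) > 0L) {
    rlang::abort(paste0("gene(s) outside the lectin universe: ", .id_list(stray)))
  }
  tandem <- universe %in% tandem_genes
  segmental <- universe %in% segmental_genes
  mechanism <- dplyr::case_when(
    tandem & segmental ~ "both",
    tandem ~ "tandem_only",
    segmental ~ "segmental_only",
    .default = "other"
  )
  labels <- tibble::tibble(gene_id = universe, mechanism = mechanism)
  levels <- c("tandem_only", "segmental_only", "both", "other")
  n <- vapply(levels, function(l) sum(mechanism == l), integer(1))
  summary <- tibble::tibble(
    mechanism = levels,
    n_genes = unname(n),
    percentage = if (length(universe) == 0L) rep(0, 4) else {
      round_half_up(100 * unname(n) / length(universe), 1)
    }
  )
  structure(list(labels = labels, summary = summary),
            class = "mechanism_partition")
}

#' Per-family mechanism-contribution table
#'
#' One row per family with the share of its genes in each mechanism class
#' (percent of the family's gene count, one decimal, half-up). Families
#' with zero genes emit zeros.
#'
#' @param partition a `mechanism_partition` from [attribute_mechanisms()].
#' @param assignments assignment tibble (gene to family).
#' @param families family universe to report; defaults to the families
#'   present in `assignments`.
#' @return tibble `family`, `n_genes`, `tandem_only`, `segmental_only`,
#'   `both`, `other` (percentages).
#' @export
family_mechanism_table <- function(partition, assignments,
                                   families = sort(unique(assignments$family))) {
  lab <- dplyr::left_join(assignments[, c("gene_id", "family")],
                          partition$labels, by = "gene_id")
  levels <- c("tandem_only", "segmental_only", "both", "other")
  rows <- purrr::map(families, function(f) {
    m <- lab$mechanism[lab$family == f]
    n <- length(m)
    shares <- if (n == 0L) rep(0, 4) else {
      unname(round_half_up(
        100 * vapply(levels, function(l) sum(m == l), integer(1)) / n, 1))
    }
    tibble::tibble(family = f, n_genes = n,
                   tandem_only = shares[1], segmental_only = shares[2],
                   both = shares[3], other = shares[4])
  })
  dplyr::bind_rows(rows)
}
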