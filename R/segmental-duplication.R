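#' Filter collinear gene pairs by synonymous substitution rate
#'
#' Pairs whose Ks exceeds `ks_max` are excluded because synonymous sites
#' saturate and the pair's duplication signal is unreliable; the boundary is
#' inclusive on the retained side ("higher than" is excluded, so Ks exactly
#' equal to `ks_max` is retained). Pairs with a missing Ks are excluded
#' conservatively, with reason `"missing"`.
#'
#' @param pairs tibble from [read_collinearity()] (`block_id`, `gene_a`,
#'   `gene_b`, `ks`).
#' @param ks_max maximum Ks retained; default 1.0; must be > 0.
#' @return list with `retained` (tibble of pairs) and `excluded` (same
#'   columns plus `reason` in `{"ks_above_max", "missing"}`).
#' @export
filter_pairs_by_ks <- function(pairs, ks_max = 1.0) {
  if (!is.numeric(ks_max) || ks_max <= 0) {
    rlang::abort("ks_max must be a positive number")
  }
  keep <- !is.na(pairs$ks) & pairs$ks <= ks_max
  excluded <- pairs[!keep, , drop = FALSE]
  excluded$reason <- ifelse(is.na(excluded$ks), "missing", "ks_above_max")
  list(retained = pairs[keep, , drop = FALSE], excluded = excluded)
}

#' Assign segmentally duplicated lectin genes from retained collinear pairs
#'
#' A lectin gene is segmentally duplicated when it appears at either end of
#' at least one retained collinear pair (blocks may pair a lectin gene with
#' a non-lectin partner). Also reports the collinear blocks contributing
#' such a pair, and the lectin genes excluded by the Ks filter, i.e. genes
#' whose every collinear pair was excluded.
#'
#' @param filtered either the list returned by [filter_pairs_by_ks()] or a
#'   tibble of retained pairs.
#' @param lectin_gene_ids character vector of lectin gene ids.
#' @return list of class `segmental_assignment`: `segmental_genes`
#'   (character), `blocks_with_lectins` (character), `excluded_pairs`
#'   (tibble, possibly empty), `excluded_genes` (lectin genes appearing only
#'   in excluded pairs), `excluded_gene_count`.
#' @export
assign_segmental <- function(filtered, lectin_gene_ids) {
  if (is.data.frame(filtered)) {
    filtered <- list(retained = filtered,
                     excluded = filtered[0, , drop = FALSE])
  }
  retained <- filtered$retained
  excluded <- filtered$excluded
  hit <- retained$gene_a %in% lectin_gene_ids | retained$gene_b %in% lectin_gene_ids
  seg_genes <- sort(unique(intersect(
    c(retained$gene_a, retained$gene_b), lectin_gene_ids
  )))
  blocks <- sort(unique(retained$block_id[hit]))
  excl_candidates <- sort(unique(intersect(
    c(excluded$gene_a, excluded$gene_b), lectin_gene_ids
  )))
  excl_genes <- setdiff(excl_candidates, seg_genes)
  structure(list(
    segmental_genes = seg_genes,
    blocks_with_lectins = blocks,
    excluded_pairs = excluded,
    excluded_genes = excl_genes,
    excluded_gene_count = length(excl_genes)
  ), class = "segmental_assignment")
}

#' Summarise segmental duplication per family
#'
#' @param segmental a `segmental_assignment` from [assign_segmental()].
#' @param assignments assignment tibble (gene to family).
#' @return tibble `family`, `n_genes_involved`, with a `total` row counting
#'   distinct genes.
#' @export
summarize_segmental <- function(segmental, assignments) {
  fams <- sort(unique(assignments$family))
  seg <- assignments[assignments$gene_id %in% segmental$segmental_genes, , drop = FALSE]
  counts <- dplyr::count(seg, .data$family, name = "n_genes_involved")
  out <- dplyr::left_join(tibble::tibble(family = fams), counts, by = "family")
  out$n_genes_involved[is.na(out$n_genes_involved)] <- 0L
  dplyr::bind_rows(out, tibble::tibble(
    family = "total",
    n_genes_involved = length(unique(seg$gene_id))
  ))
}
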