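#' Detect tandem-duplication clusters
#'
#' A tandem cluster is a maximal chain of genes that (1) belong to the same
#' lectin family, (2) lie on the same chromosome, and (3) have no more than
#' `max_intervening` intervening genes between consecutive members. The
#' intervening count between genes with ranks r1 < r2 is `r2 - r1 - 1`,
#' counted by default over ALL annotated genes (lectin or not), which is the
#' physical gene-neighbourhood reading; `intervening = "lectin"` counts only
#' lectin genes instead. Chaining is transitive: if A links B and B links C,
#' the cluster is {A, B, C} even when A and C are farther apart than the
#' threshold. Unplaced (scaffold) genes never join clusters.
#'
#' @param genes gene tibble from [read_gene_annotation()] (ranks assigned).
#' @param assignments assignment tibble resolving each lectin gene to one
#'   (primary) family.
#' @param max_intervening maximum number of intervening genes between
#'   consecutive cluster members; default 10.
#' @param intervening `"all"` (default): count every annotated gene between
#'   two members; `"lectin"`: count only lectin genes.
#' @return tibble with `cluster_id`, `family`, `chromosome`, `n_members`,
#'   and list-columns `members` (gene ids in rank order) and `gaps`
#'   (intervening-gene counts between consecutive members).
#' @export
detect_tandem_clusters <- function(genes, assignments, max_intervening = 10L,
                                   intervening = c("all", "lectin")) {
  intervening <- match.arg(intervening)
  if (max_intervening < 0) {
    rlang::abort("max_intervening must be >= 0")
  }
  lect <- dplyr::inner_join(assignments[, c("gene_id", "family")],
                            genes[, c("gene_id", "chromosome", "rank", "is_placed")],
                            by = "gene_id")
  lect <- lect[lect$is_placed, , drop = FALSE]
  if (nrow(lect) == 0L) return(.empty_clusters())
  if (intervening == "lectin") {
    lect <- dplyr::mutate(
      dplyr::group_by(dplyr::arrange(lect, .data$chromosome, .data$rank), .data$chromosome),
      rank = dplyr::row_number() - 1L
    )
    lect <- dplyr::ungroup(lect)
  }
  lect <- dplyr::arrange(lect, .data$family, .data$chromosome, .data$rank)
  key <- paste(lect$family, lect$chromosome, sep = "\r")
  out <- list()
  for (k in unique(key)) {
    g <- lect[key == k, , drop = FALSE]
    if (nrow(g) < 2L) next
    gaps <- diff(g$rank) - 1L
    brk <- cumsum(c(0L, as.integer(gaps > max_intervening)))
    for (b in unique(brk)) {
      idx <- which(brk == b)
      if (length(idx) < 2L) next
      out[[length(out) + 1L]] <- tibble::tibble(
        family = g$family[idx[1]],
        chromosome = g$chromosome[idx[1]],
        n_members = length(idx),
        members = list(g$gene_id[idx]),
        gaps = list(gaps[idx[-length(idx)]])
      )
    }
  }
  if (length(out) == 0L) return(.empty_clusters())
  clusters <- dplyr::bind_rows(out)
  clusters <- dplyr::arrange(clusters, .data$family, .data$chromosome)
  clusters <- dplyr::mutate(
    dplyr::group_by(clusters, .data$family),
    cluster_id = paste0(.data$family, "_", .data$chromosome, "_",
                        formatC(dplyr::row_number(), width = 2, flag = "0"))
  )
  dplyr::relocate(dplyr::ungroup(clusters), "cluster_id")
}

.empty_clusters <- function() {
  tibble::tibble(cluster_id = character(), family = character(),
                 chromosome = character(), n_members = integer(),
                 members = list(), gaps = list())
}

#' Summarise tandem clusters per family
#'
#' Per-family number of clusters and number of distinct genes involved,
#' with a `total` row. Families present in the assignment table but without
#' clusters are reported with zeros.
#'
#' @param clusters tibble from [detect_tandem_clusters()].
#' @param assignments assignment tibble; fixes the family universe.
#' @return tibble `family`, `n_clusters`, `n_genes_involved`, last row
#'   `family = "total"`.
#' @export
summarize_tandem <- function(clusters, assignments) {
  fams <- sort(unique(assignments$family))
  per <- purrr::map(fams, function(f) {
    cl <- clusters[clusters$family == f, , drop = FALSE]
    tibble::tibble(
      family = f,
      n_clusters = nrow(cl),
      n_genes_involved = length(unique(unlist(cl$members)))
    )
  })
  out <- dplyr::bind_rows(per)
  dplyr::bind_rows(out, tibble::tibble(
    family = "total",
    n_clusters = sum(out$n_clusters),
    n_genes_involved = sum(out$n_genes_involved)
  ))
}
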