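#' Summarise lectin genes per family
#'
#' Produces the per-family gene count and percentage of all lectin genes,
#' reporting all twelve families including those with zero genes.
#' Percentages are rounded half-up to one decimal so the printed values are
#' stable (e.g. 3/359 -> 0.8). When a gene table is supplied, each family's
#' chromosome-localisation string is added.
#'
#' @param x either an assignment tibble (with `gene_id` and `family`
#'   columns, one row per gene) or a precomputed count table with columns
#'   `family` and `n_genes`.
#' @param genes optional gene tibble from [read_gene_annotation()]; enables
#'   the `chromosomes` localisation column (placed genes only).
#' @param families family universe to report; defaults to the twelve
#'   canonical lectin families.
#' @param chromosome_universe chromosome labels used for the "all except"
#'   localisation convention; default `chr1..chr20`.
#' @return tibble `family`, `n_genes`, `percentage` (one decimal), and
#'   `chromosomes` when `genes` is given. A zero-gene universe yields 0.0
#'   percentages with a warning.
#' @export
summarize_families <- function(x, genes = NULL, families = lectin_family_names(),
                               chromosome_universe = paste0("chr", 1:20)) {
  if (all(c("family", "n_genes") %in% names(x)) && !("gene_id" %in% names(x))) {
    counts <- x[, c("family", "n_genes")]
  } else {
    counts <- dplyr::count(x, .data$family, name = "n_genes")
  }
  unknown <- setdiff(counts$family, families)
  if (length(unknown) > 0L) {
    rlang::abort(paste0("unknown family label(s): ", .id_list(unknown)))
  }
  out <- dplyr::left_join(tibble::tibble(family = families), counts, by = "family")
  out$n_genes[is.na(out$n_genes)] <- 0L
  total <- sum(out$n_genes)
  if (total == 0L) {
    rlang::warn("no lectin genes; percentages reported as 0.0")
    out$percentage <- 0
  } else {
    out$percentage <- round_half_up(100 * out$n_genes / total, 1)
  }
  if (!is.null(x) && "gene_id" %in% names(x) && !is.null(genes)) {
    placed <- genes[genes$is_placed, c("gene_id", "chromosome")]
    occ <- dplyr::inner_join(x[, c("gene_id", "family")], placed, by = "gene_id")
    out$chromosomes <- purrr::map_chr(out$family, function(f) {
      localization_string(unique(occ$chromosome[occ$family == f]), chromosome_universe)
    })
  }
  out
}

#' Human-readable chromosome localisation of a family
#'
#' Families occupying more than `all_except_threshold` of the chromosome
#' universe are described by what they lack ("all except chr 5"); smaller
#' occupancies list the chromosomes ("13, 15, 17"); an empty family gives
#' `"/"`. Chromosome numbers are extracted from `chrN` labels; non-numeric
#' labels are listed verbatim after the numeric ones.
#'
#' @param occupied character vector of occupied chromosome labels.
#' @param universe character vector of all chromosome labels.
#' @param all_except_threshold occupancy fraction above which the
#'   "all except" form is used; default 0.5.
#' @return a single string.
#' @export
localization_string <- function(occupied, universe = paste0("chr", 1:20),
                                all_except_threshold = 0.5) {
  occupied <- unique(occupied[occupied %in% universe])
  if (length(occupied) == 0L) return("/")
  if (length(occupied) == length(universe)) return("all")
  if (length(occupied) / length(universe) > all_except_threshold) {
    missing <- .sort_chromosomes(setdiff(universe, occupied))
    labels <- sub("^chr", "chr ", missing)
    joined <- if (length(labels) == 1L) {
      labels
    } else if (length(labels) == 2L) {
      paste(labels, collapse = " and ")
    } else {
      paste0(paste(labels[-length(labels)], collapse = ", "), " and ", labels[length(labels)])
    }
    return(paste0("all except ", joined))
  }
  paste(sub("^chr", "", .sort_chromosomes(occupied)), collapse = ", ")
}

# numeric chrN labels in numeric order, then anything else lexicographically
.sort_chromosomes <- function(x) {
  num <- suppressWarnings(as.integer(sub("^chr", "", x)))
  c(x[!is.na(num)][order(num[!is.na(num)])], sort(x[is.na(num)]))
}

#' Per-chromosome share of lectin genes
#'
#' Counts placed lectin genes per chromosome and their percentage of the
#' total, rounded half-up to one decimal. The denominator defaults to the
#' placed lectin genes; `denominator = "all"` uses every assigned lectin
#' gene including those on unmapped scaffolds.
#'
#' @param assignments assignment tibble (one row per gene).
#' @param genes gene tibble from [read_gene_annotation()].
#' @param chromosome_universe chromosomes to report (zeros included).
#' @param denominator `"placed"` (default) or `"all"`.
#' @return tibble `chromosome`, `n_genes`, `percentage`.
#' @export
chromosome_shares <- function(assignments, genes,
                              chromosome_universe = paste0("chr", 1:20),
                              denominator = c("placed", "all")) {
  denominator <- match.arg(denominator)
  placed <- genes[genes$is_placed, c("gene_id", "chromosome")]
  occ <- dplyr::inner_join(assignments[, "gene_id", drop = FALSE], placed, by = "gene_id")
  counts <- dplyr::count(occ, .data$chromosome, name = "n_genes")
  out <- dplyr::left_join(tibble::tibble(chromosome = chromosome_universe),
                          counts, by = "chromosome")
  out$n_genes[is.na(out$n_genes)] <- 0L
  denom <- if (denominator == "placed") nrow(occ) else nrow(assignments)
  out$percentage <- if (denom == 0L) 0 else round_half_up(100 * out$n_genes / denom, 1)
  out
}

#' Chromosome-map coordinates for plotting
#'
#' One row per placed lectin gene with its drawn-to-scale position (gene
#' start, bp), family, and whether it belongs to a tandem-duplication
#' cluster. Unplaced genes are absent. Centromere positions, when given,
#' are appended as rows with `family = "centromere"`.
#'
#' @param genes gene tibble from [read_gene_annotation()].
#' @param assignments assignment tibble (one row per gene).
#' @param clusters optional tandem-cluster tibble from
#'   [detect_tandem_clusters()]; flags member genes.
#' @param centromeres optional tibble with `chromosome`, `position`.
#' @return tibble `chromosome`, `position`, `gene_id`, `family`,
#'   `tandem_flag`.
#' @export
map_coordinates <- function(genes, assignments, clusters = NULL, centromeres = NULL) {
  placed <- genes[genes$is_placed, c("gene_id", "chromosome", "start")]
  out <- dplyr::inner_join(assignments[, c("gene_id", "family")], placed, by = "gene_id")
  tandem_ids <- if (is.null(clusters) || nrow(clusters) == 0L) character(0) else {
    unique(unlist(clusters$members))
  }
  out <- tibble::tibble(
    chromosome = out$chromosome,
    position = out$start,
    gene_id = out$gene_id,
    family = out$family,
    tandem_flag = out$gene_id %in% tandem_ids
  )
  if (!is.null(centromeres)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      chromosome = centromeres$chromosome,
      position = centromeres$position,
      gene_id = NA_character_,
      family = "centromere",
      tandem_flag = FALSE
    ))
  }
  dplyr::arrange(out, .data$chromosome, .data$position)
}
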