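#' Read gene annotation from GFF3 and assign chromosome gene order
#'
#' Reads rows of feature type `"gene"` from a GFF3 file and builds the gene
#' table every downstream stage relies on: one row per gene with its
#' chromosome, 1-based inclusive coordinates, strand, and `rank` -- the
#' 0-based position of the gene in start-sorted order within its chromosome.
#' Ranks are the basis for counting "intervening genes" in tandem-duplication
#' detection.
#'
#' Gene order is defined by the smaller genomic coordinate (`start`), with
#' ties broken by `end` then `gene_id`, so ordering depends only on
#' coordinates, never on file row order. Set `order_by = "tss"` to order by
#' strand-aware transcription start instead (`end` for minus-strand genes).
#'
#' @param path path to a GFF3 file (plain or gzip).
#' @param placed_pattern regular expression matched against the seqid to
#'   decide whether a gene is on a placed chromosome; non-matching seqids
#'   (unmapped scaffolds) get `is_placed = FALSE`. Unplaced genes keep ranks
#'   within their own scaffold but are excluded from tandem detection and
#'   chromosome maps downstream.
#' @param order_by `"start"` (default, smaller coordinate) or `"tss"`
#'   (strand-aware transcript start).
#' @return tibble with columns `gene_id`, `chromosome`, `start`, `end`,
#'   `strand`, `rank`, `is_placed`, sorted by `(chromosome, start)`.
#' @export
read_gene_annotation <- function(path, placed_pattern = "^chr[0-9]+$",
                                 order_by = c("start", "tss")) {
  order_by <- match.arg(order_by)
  gff <- ape::read.gff(path, GFF3 = TRUE)
  gff <- gff[gff$type == "gene", , drop = FALSE]
  if (nrow(gff) == 0L) {
    rlang::abort("no 'gene' features found in GFF3 input")
  }
  gene_id <- stringr::str_match(gff$attributes, "(?:^|;)\\s*ID=([^;]+)")[, 2]
  if (anyNA(gene_id)) {
    rlang::abort("GFF3 gene rows without an ID attribute")
  }
  genes <- tibble::tibble(
    gene_id    = gene_id,
    chromosome = as.character(gff$seqid),
    start      = as.integer(gff$start),
    end        = as.integer(gff$end),
    strand     = as.character(gff$strand)
  )
  genes$strand[is.na(genes$strand) | !genes$strand %in% c("+", "-")] <- "."
  bad <- genes$gene_id[genes$start > genes$end]
  if (length(bad) > 0L) {
    rlang::abort(paste0("malformed coordinates (start > end) for: ", .id_list(bad)))
  }
  dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dup) > 0L) {
    rlang::abort(paste0("duplicate gene_id: ", .id_list(dup)))
  }
  assign_gene_ranks(genes, placed_pattern = placed_pattern, order_by = order_by)
}

#' Assign within-chromosome gene ranks
#'
#' Deterministic ordering key: position (start, or strand-aware TSS), then
#' end, then gene_id. Ranks are consecutive 0-based integers within each
#' chromosome.
#'
#' @param genes tibble with `gene_id`, `chromosome`, `start`, `end`, `strand`.
#' @inheritParams read_gene_annotation
#' @return the input with `rank` and `is_placed` columns, sorted by
#'   `(chromosome, start)`.
#' @export
assign_gene_ranks <- function(genes, placed_pattern = "^chr[0-9]+$",
                              order_by = c("start", "tss")) {
  order_by <- match.arg(order_by)
  pos <- if (order_by == "tss") {
    ifelse(genes$strand == "-", genes$end, genes$start)
  } else {
    genes$start
  }
  genes$.pos <- pos
  genes <- dplyr::arrange(genes, .data$chromosome, .data$.pos, .data$end, .data$gene_id)
  genes <- dplyr::mutate(
    dplyr::group_by(genes, .data$chromosome),
    rank = dplyr::row_number() - 1L
  )
  genes <- dplyr::ungroup(genes)
  genes$is_placed <- grepl(placed_pattern, genes$chromosome)
  genes$.pos <- NULL
  dplyr::arrange(genes, .data$chromosome, .data$start)
}

#' Read a protein domain-hit table
#'
#' Reads an InterProScan-style TSV with one domain hit per row. Mandatory
#' columns: `protein_id`, `domain_accession`, `description`, `d_start`,
#' `d_end`, `score` (an E-value or bit score; the classifier decides the
#' direction). Coordinates are 1-based inclusive amino-acid positions.
#'
#' Rows whose coordinates cannot be parsed as positive integers with
#' `d_start <= d_end` are dropped with a warning stating how many.
#'
#' @param path path to the TSV file.
#' @return tibble of hits sorted by `(protein_id, d_start)`.
#' @export
read_domain_table <- function(path) {
  hits <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                          na = c("", "NA"), progress = FALSE)
  required <- c("protein_id", "domain_accession", "description", "d_start", "d_end", "score")
  missing <- setdiff(required, names(hits))
  if (length(missing) > 0L) {
    rlang::abort(paste0("domain table is missing mandatory column(s): ",
                        paste(missing, collapse = ", ")))
  }
  d_start <- suppressWarnings(as.integer(hits$d_start))
  d_end <- suppressWarnings(as.integer(hits$d_end))
  ok <- !is.na(d_start) & !is.na(d_end) & d_start >= 1L & d_start <= d_end
  n_bad <- sum(!ok)
  if (n_bad > 0L) {
    rlang::warn(paste0("dropped ", n_bad, " domain hit(s) with unparseable coordinates"))
  }
  out <- tibble::tibble(
    protein_id       = hits$protein_id[ok],
    domain_accession = hits$domain_accession[ok],
    description      = hits$description[ok],
    d_start          = d_start[ok],
    d_end            = d_end[ok],
    score            = suppressWarnings(as.numeric(hits$score[ok]))
  )
  dplyr::arrange(out, .data$protein_id, .data$d_start, .data$d_end, .data$domain_accession)
}

#' Read signal-peptide / transmembrane topology annotations
#'
#' Reads a TSV with columns `protein_id`, `signal_peptide` (logical or 0/1)
#' and `tm_segments` -- a `;`-separated list of `start-end` amino-acid
#' intervals, empty or `NA` when the protein has no predicted transmembrane
#' segment.
#'
#' N-terminal transmembrane predictions frequently are the signal peptide's
#' hydrophobic core seen twice; a TM segment that lies entirely within the
#' first `sp_window` residues of a protein that also has a signal peptide is
#' therefore discarded, mirroring the manual double-check such predictions
#' receive in practice.
#'
#' @param path path to the TSV file.
#' @param sp_window N-terminal window (aa) for suppressing TM segments that
#'   overlap a signal peptide. Default 30.
#' @return tibble with `protein_id`, `has_signal_peptide`, and list-column
#'   `tm_segments` of two-column matrices (`start`, `end`), sorted and
#'   non-overlapping.
#' @export
read_topology_table <- function(path, sp_window = 30L) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "NA"), progress = FALSE)
  required <- c("protein_id", "signal_peptide", "tm_segments")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    rlang::abort(paste0("topology table is missing mandatory column(s): ",
                        paste(missing, collapse = ", ")))
  }
  sp <- tab$signal_peptide %in% c("TRUE", "true", "1", "yes")
  segs <- purrr::map2(tab$tm_segments, sp, function(s, has_sp) {
    if (is.na(s) || !nzchar(s)) {
      return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
    }
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
    m <- do.call(rbind, lapply(parts, function(p) as.integer(p[1:2])))
    colnames(m) <- c("start", "end")
    if (anyNA(m) || any(m[, 1] > m[, 2])) {
      rlang::abort("malformed tm_segments interval; expected 'start-end;start-end'")
    }
    m <- m[order(m[, 1]), , drop = FALSE]
    if (nrow(m) > 1L && any(m[-1, 1] <= m[-nrow(m), 2])) {
      rlang::abort("overlapping tm_segments for a protein")
    }
    if (has_sp) {
      m <- m[!(m[, 1] >= 1L & m[, 2] <= sp_window), , drop = FALSE]
    }
    m
  })
  tibble::tibble(
    protein_id         = tab$protein_id,
    has_signal_peptide = sp,
    tm_segments        = segs
  )
}

#' Read a collinearity file with per-pair Ks values
#'
#' Parses MCScanX-style text: block header lines starting with
#' `## Alignment` (everything after `Alignment` up to `:` is the block id),
#' followed by one gene pair per line. A pair line may begin with an index
#' token such as `0-  3:`; the first two remaining fields are the two gene
#' ids and the last field is the Ks value (`NA` for missing). Comment lines
#' starting with `#` (but not `##`) are ignored.
#'
#' A pair's identity is block-scoped and orientation-free: within a block,
#' `(a,b)` and `(b,a)` are the same pair and only the first occurrence is
#' kept; the same pair in two different blocks yields two records.
#'
#' @param path path to the collinearity text file.
#' @return tibble with `block_id`, `gene_a`, `gene_b`, `ks` (`NA` = missing).
#' @export
read_collinearity <- function(path) {
  lines <- readLines(path, warn = FALSE)
  block <- NA_character_
  out <- vector("list", length(lines))
  n_out <- 0L
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    if (grepl("^##\\s*Alignment", line)) {
      block <- trimws(sub(":.*$", "", sub("^##\\s*Alignment\\s*", "", line)))
      next
    }
    if (startsWith(line, "#")) next
    if (is.na(block)) {
      rlang::abort(paste0("line ", i, ": pair line before any '## Alignment' header"))
    }
    fields <- strsplit(line, "[\t ]+")[[1]]
    # optional leading pair-index token like "12-  3:"
    if (grepl(":$", fields[1]) || grepl("^[0-9]+-$", fields[1])) {
      fields <- fields[-1]
      while (length(fields) > 0L && grepl(":$", fields[1])) fields <- fields[-1]
    }
    if (length(fields) < 3L) {
      rlang::abort(paste0("line ", i, ": pair line has fewer fields than required ",
                          "(gene_a, gene_b, ..., ks)"))
    }
    ks_raw <- fields[length(fields)]
    ks <- if (identical(ks_raw, "NA")) NA_real_ else suppressWarnings(as.numeric(ks_raw))
    n_out <- n_out + 1L
    out[[n_out]] <- list(block_id = block, gene_a = fields[1], gene_b = fields[2], ks = ks)
  }
  if (n_out == 0L) {
    return(tibble::tibble(block_id = character(), gene_a = character(),
                          gene_b = character(), ks = numeric()))
  }
  pairs <- dplyr::bind_rows(out[seq_len(n_out)])
  if (any(pairs$gene_a == pairs$gene_b)) {
    rlang::abort("self-pair (gene_a == gene_b) in collinearity input")
  }
  key <- paste(pairs$block_id,
               pmin(pairs$gene_a, pairs$gene_b),
               pmax(pairs$gene_a, pairs$gene_b), sep = "\r")
  pairs[!duplicated(key), , drop = FALSE]
}

#' Write a result table as TSV
#'
#' Writes a tibble with a header, a stable column order given by `schema`,
#' and `NA` for missing values. List-columns are collapsed with `","` so
#' every table round-trips through [read_table_tsv()].
#'
#' @param rows tibble to write.
#' @param path output path.
#' @param schema optional character vector naming (and ordering) the columns
#'   to write; every schema column must exist in `rows`.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, schema = NULL) {
  if (!is.null(schema)) {
    missing <- setdiff(schema, names(rows))
    if (length(missing) > 0L) {
      rlang::abort(paste0("schema column(s) absent from rows: ",
                          paste(missing, collapse = ", ")))
    }
    rows <- rows[, schema, drop = FALSE]
  }
  rows <- dplyr::mutate(rows, dplyr::across(
    dplyr::where(is.list),
    ~ purrr::map_chr(.x, function(v) paste(v, collapse = ","))
  ))
  readr::write_tsv(rows, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read back a TSV written by [write_table()]
#'
#' @param path path to the TSV.
#' @return tibble with column types guessed from the contents.
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, na = "NA", show_col_types = FALSE, progress = FALSE)
}
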