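#' Load lectin family definitions and the domain-token vocabulary
#'
#' Reads a YAML config mapping domain accessions to the twelve plant lectin
#' families (with a reference domain length and truncation fraction per
#' family) plus a controlled vocabulary for non-lectin architecture tokens.
#' The packaged default ships Pfam accessions where the lectin domain has
#' one and synthetic placeholders for the families identified by alignment
#' only (EUL, Nictaba, CRA).
#'
#' @param path path to a YAML config; `NULL` (default) loads the packaged one.
#' @return list with elements `families` (tibble: `family`, list-column
#'   `accessions`, `reference_domain_length`, `truncation_fraction`) and
#'   `tokens` (tibble: `accession`, `token`, `length`).
#' @export
lectin_family_definitions <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "lectin_families.yaml", package = "lectinscape")
  }
  cfg <- yaml::read_yaml(path)
  fams <- tibble::tibble(
    family = names(cfg$families),
    accessions = purrr::map(cfg$families, ~ as.character(.x$accessions)),
    reference_domain_length = purrr::map_int(cfg$families, ~ as.integer(.x$reference_domain_length)),
    truncation_fraction = purrr::map_dbl(cfg$families, ~ as.numeric(.x$truncation_fraction))
  )
  acc <- unlist(fams$accessions)
  dup <- unique(acc[duplicated(acc)])
  if (length(dup) > 0L) {
    rlang::abort(paste0("domain accession claimed by two families: ", .id_list(dup)))
  }
  tokens <- tibble::tibble(
    accession = names(cfg$tokens),
    token = purrr::map_chr(cfg$tokens, ~ as.character(.x$token)),
    length = purrr::map_int(cfg$tokens, ~ as.integer(.x$length))
  )
  list(families = fams, tokens = tokens)
}

# accession -> family lookup (named character vector)
.accession_family_map <- function(defs) {
  fams <- defs$families
  stats::setNames(rep(fams$family, lengths(fams$accessions)), unlist(fams$accessions))
}

#' Flag a truncated lectin domain
#'
#' A domain hit is truncated when its observed length (aa) is strictly less
#' than `fraction` times the family's reference domain length. Hits exactly
#' at the threshold are not flagged.
#'
#' @param observed_length observed hit length in amino acids
#'   (`d_end - d_start + 1`); vectorised.
#' @param reference_length the family's reference domain length (aa), > 0.
#' @param fraction truncation fraction in (0, 1]; default 0.75.
#' @return logical vector.
#' @export
flag_truncated <- function(observed_length, reference_length, fraction = 0.75) {
  stopifnot(reference_length > 0, fraction > 0, fraction <= 1)
  observed_length < fraction * reference_length
}

#' Build the canonical N-to-C domain-architecture token list for one protein
#'
#' Tokens are the protein's domain hits translated through the family
#' definitions (lectin domains become their family label, e.g. `"GNA"`) and
#' the token vocabulary (other known domains, e.g. `"kinase"`); unknown
#' accessions keep their accession as token. Transmembrane segments are
#' interleaved as `"TM"` tokens at their coordinate position, and `"SP"` is
#' prepended when the protein has a signal peptide. Overlapping hits of the
#' same accession are merged into one token; overlapping hits of different
#' accessions are both kept, ordered by start then accession.
#'
#' @param hits tibble of domain hits for one protein (columns
#'   `domain_accession`, `d_start`, `d_end`).
#' @param defs output of [lectin_family_definitions()].
#' @param has_signal_peptide logical scalar.
#' @param tm_segments two-column matrix of TM intervals (aa), possibly empty.
#' @return character vector of tokens in N-to-C order (possibly empty).
#' @export
build_architecture <- function(hits, defs, has_signal_peptide = FALSE,
                               tm_segments = NULL) {
  acc2fam <- .accession_family_map(defs)
  acc2tok <- stats::setNames(defs$tokens$token, defs$tokens$accession)
  units <- NULL
  if (!is.null(hits) && nrow(hits) > 0L) {
    merged <- dplyr::summarise(
      dplyr::group_by(hits, .data$domain_accession,
                      grp = .merge_group(.data$d_start, .data$d_end, .data$domain_accession)),
      d_start = min(.data$d_start), d_end = max(.data$d_end), .groups = "drop"
    )
    tok <- ifelse(merged$domain_accession %in% names(acc2fam),
                  unname(acc2fam[merged$domain_accession]),
                  ifelse(merged$domain_accession %in% names(acc2tok),
                         unname(acc2tok[merged$domain_accession]),
                         merged$domain_accession))
    units <- tibble::tibble(token = tok, pos = merged$d_start, tie = merged$domain_accession)
  }
  if (!is.null(tm_segments) && nrow(tm_segments) > 0L) {
    units <- dplyr::bind_rows(units, tibble::tibble(
      token = "TM", pos = as.integer(tm_segments[, 1]), tie = "TM"
    ))
  }
  tokens <- character(0)
  if (!is.null(units) && nrow(units) > 0L) {
    units <- dplyr::arrange(units, .data$pos, .data$tie)
    tokens <- units$token
  }
  if (isTRUE(has_signal_peptide)) tokens <- c("SP", tokens)
  tokens
}

# group id for merging overlapping same-accession intervals; input assumed
# grouped by accession downstream, so key on accession + chain of overlaps
.merge_group <- function(s, e, acc) {
  o <- order(acc, s, e)
  g <- integer(length(s))
  gi <- 0L
  last_acc <- NA_character_
  last_end <- -Inf
  for (k in o) {
    if (!identical(acc[k], last_acc) || s[k] > last_end) {
      gi <- gi + 1L
      last_end <- e[k]
    } else {
      last_end <- max(last_end, e[k])
    }
    last_acc <- acc[k]
    g[k] <- gi
  }
  g
}

#' Join architecture tokens into the canonical string / parse it back
#'
#' The canonical architecture string joins tokens with `"|"`; parsing is the
#' exact inverse, so `parse_architecture(architecture_string(tokens))`
#' returns `tokens`.
#'
#' @param tokens character vector of tokens.
#' @return `architecture_string()`: a single string (empty for no tokens).
#' @export
architecture_string <- function(tokens) {
  paste(tokens, collapse = "|")
}

#' @rdname architecture_string
#' @param string a canonical architecture string.
#' @export
parse_architecture <- function(string) {
  if (!nzchar(string)) return(character(0))
  strsplit(string, "|", fixed = TRUE)[[1]]
}

#' Assign genes to lectin families and build their domain architectures
#'
#' A gene joins family F iff it has at least one domain hit whose accession
#' belongs to F. Genes with no lectin-domain hit are excluded from the
#' output entirely. Genes with hits from two or more lectin families are
#' flagged `multi_family`; in the default `"primary"` mode each such gene is
#' counted once, under the family of its best-scoring lectin hit (so
#' per-family counts stay additive), with a warning. In `"strict"` mode the
#' gene contributes one row per family, which breaks additivity.
#'
#' @param hits tibble of domain hits (from [read_domain_table()]); one
#'   protein per gene is assumed, so `protein_id` doubles as the gene id.
#' @param defs output of [lectin_family_definitions()].
#' @param topology optional tibble from [read_topology_table()]; supplies
#'   SP/TM tokens for the architecture strings.
#' @param multi_family `"primary"` (default) or `"strict"`; see Details.
#' @param score_type `"evalue"` (lower is better, default) or `"bitscore"`
#'   (higher is better); decides the best hit for primary-family choice.
#' @return tibble with one row per (gene, assigned family): `gene_id`,
#'   `family` (primary in `"primary"` mode), `families` (comma-joined full
#'   set), `multi_family`, `architecture` (canonical string),
#'   `has_signal_peptide`, `n_tm`, `n_truncated`.
#' @export
assign_families <- function(hits, defs, topology = NULL,
                            multi_family = c("primary", "strict"),
                            score_type = c("evalue", "bitscore")) {
  multi_family <- match.arg(multi_family)
  score_type <- match.arg(score_type)
  acc2fam <- .accession_family_map(defs)
  fams <- defs$families
  ref_len <- stats::setNames(fams$reference_domain_length, fams$family)
  trunc_frac <- stats::setNames(fams$truncation_fraction, fams$family)

  topo_sp <- topo_tm <- NULL
  if (!is.null(topology)) {
    topo_sp <- stats::setNames(topology$has_signal_peptide, topology$protein_id)
    topo_tm <- stats::setNames(topology$tm_segments, topology$protein_id)
  }

  lectin_ids <- unique(hits$protein_id[hits$domain_accession %in% names(acc2fam)])
  rows <- purrr::map(lectin_ids, function(gid) {
    h <- hits[hits$protein_id == gid, , drop = FALSE]
    lh <- h[h$domain_accession %in% names(acc2fam), , drop = FALSE]
    lh$family <- unname(acc2fam[lh$domain_accession])
    fam_set <- sort(unique(lh$family))
    better <- if (score_type == "evalue") order(lh$score) else order(-lh$score)
    primary <- lh$family[better[1]]
    sp <- isTRUE(topo_sp[[gid]])
    tm <- if (!is.null(topo_tm) && gid %in% names(topo_tm)) topo_tm[[gid]] else NULL
    tokens <- build_architecture(h, defs, has_signal_peptide = sp, tm_segments = tm)
    obs_len <- lh$d_end - lh$d_start + 1L
    truncated <- flag_truncated(obs_len, ref_len[lh$family], trunc_frac[lh$family])
    tibble::tibble(
      gene_id = gid,
      family = primary,
      families = paste(fam_set, collapse = ","),
      multi_family = length(fam_set) > 1L,
      architecture = architecture_string(tokens),
      has_signal_peptide = sp,
      n_tm = if (is.null(tm)) 0L else nrow(tm),
      n_truncated = sum(truncated)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble::tibble(gene_id = character(), family = character(),
                          families = character(), multi_family = logical(),
                          architecture = character(), has_signal_peptide = logical(),
                          n_tm = integer(), n_truncated = integer()))
  }
  n_multi <- sum(out$multi_family)
  if (multi_family == "primary") {
    if (n_multi > 0L) {
      rlang::warn(paste0(n_multi, " gene(s) carry lectin domains of more than one ",
                         "family; counted once under their best-scoring family"))
    }
  } else {
    out <- tidyr::separate_rows(out, "families", sep = ",")
    out$family <- out$families
  }
  dplyr::arrange(out, .data$gene_id)
}

#' Group genes by exact domain-architecture string
#'
#' @param assignments tibble from [assign_families()].
#' @return tibble `architecture`, `n_genes`, sorted by descending count then
#'   architecture string; empty input gives an empty tibble.
#' @export
group_architectures <- function(assignments) {
  if (nrow(assignments) == 0L) {
    return(tibble::tibble(architecture = character(), n_genes = integer()))
  }
  out <- dplyr::count(assignments, .data$architecture, name = "n_genes")
  dplyr::arrange(out, dplyr::desc(.data$n_genes), .data$architecture)
}
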