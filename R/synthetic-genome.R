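#' Configuration for the synthetic lectin genome simulator
#'
#' Builds and validates the parameter set for [simulate_genome()]. The
#' defaults emulate, at desk scale, the statistical structure of a
#' paleopolyploid plant genome whose lectin complement expanded by tandem
#' and segmental duplication: a background annotation of ordinary genes,
#' planted same-family tandem arrays, planted collinear blocks whose gene
#' pairs carry synonymous-substitution (Ks) values from a two-component
#' recent/ancient lognormal mixture, and per-protein domain architectures
#' drawn from the family template catalogue.
#'
#' Family proportions default to the relative sizes observed across the
#' nine non-empty plant lectin families in soybean (GNA largest, then
#' legume, then LysM, ...). `fraction_ks_above_threshold` defaults to 0.16,
#' the approximate share of collinear duplicate genes lost to Ks saturation
#' in that survey (32 of ~198). Scattered (non-array) lectin genes are
#' placed with a same-family isolation margin wider than the tandem rule's
#' window so that the planted arrays are exactly the clusters the rule can
#' find, making truth labels well defined.
#'
#' @param seed integer RNG seed; every simulator draw depends on it.
#' @param n_chromosomes number of placed chromosomes.
#' @param genes_per_chromosome background annotation size per chromosome.
#' @param family_proportions named probability vector over lectin families
#'   (must sum to 1).
#' @param n_tandem_arrays number of planted tandem arrays.
#' @param tandem_array_size_range integer `(min, max)` members per array.
#' @param tandem_spacing_range integer `(min, max)` intervening genes
#'   between consecutive array members.
#' @param n_scattered_lectins lectin genes planted outside arrays.
#' @param n_scaffold_genes lectin genes placed on unmapped scaffolds.
#' @param n_collinear_blocks number of planted collinear blocks.
#' @param block_size_range integer `(min, max)` gene pairs per block.
#' @param lectin_block_bias probability that a block is anchored on a
#'   lectin gene (the rest land anywhere).
#' @param ks_distribution list with numeric vectors `meanlog` and `sdlog`
#'   of length 2: recent component (truncated to `<= ks_max`) and ancient
#'   component (truncated to `> ks_max`).
#' @param fraction_ks_above_threshold probability that a pair draws its Ks
#'   from the ancient (saturated) component.
#' @param ks_max the saturation threshold the analysis will filter at.
#' @param max_intervening the tandem rule's window; used only to set the
#'   isolation margin between planted same-family lectin genes.
#' @param signal_peptide_rate,tm_rate rates at which background (non-lectin)
#'   proteins get a signal peptide / a transmembrane segment.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 42L,
                              n_chromosomes = 5L,
                              genes_per_chromosome = 400L,
                              family_proportions = NULL,
                              n_tandem_arrays = 12L,
                              tandem_array_size_range = c(2L, 6L),
                              tandem_spacing_range = c(0L, 8L),
                              n_scattered_lectins = 60L,
                              n_scaffold_genes = 2L,
                              n_collinear_blocks = 30L,
                              block_size_range = c(3L, 8L),
                              lectin_block_bias = 0.75,
                              ks_distribution = list(meanlog = c(-0.7, 0.6),
                                                     sdlog = c(0.45, 0.30)),
                              fraction_ks_above_threshold = 0.16,
                              ks_max = 1.0,
                              max_intervening = 10L,
                              signal_peptide_rate = 0.45,
                              tm_rate = 0.20) {
  if (is.null(family_proportions)) {
    counts <- c(CRA = 6, EUL = 3, GNA = 166, hevein = 6, jacalin = 5,
                legume = 94, LysM = 47, Nictaba = 22, `ricin B` = 10)
    family_proportions <- counts / sum(counts)
  }
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    genes_per_chromosome = as.integer(genes_per_chromosome),
    family_proportions = family_proportions,
    n_tandem_arrays = as.integer(n_tandem_arrays),
    tandem_array_size_range = as.integer(tandem_array_size_range),
    tandem_spacing_range = as.integer(tandem_spacing_range),
    n_scattered_lectins = as.integer(n_scattered_lectins),
    n_scaffold_genes = as.integer(n_scaffold_genes),
    n_collinear_blocks = as.integer(n_collinear_blocks),
    block_size_range = as.integer(block_size_range),
    lectin_block_bias = lectin_block_bias,
    ks_distribution = ks_distribution,
    fraction_ks_above_threshold = fraction_ks_above_threshold,
    ks_max = ks_max,
    max_intervening = as.integer(max_intervening),
    signal_peptide_rate = signal_peptide_rate,
    tm_rate = tm_rate
  )
  .validate_config(cfg)
  structure(cfg, class = "simulation_config")
}

.validate_config <- function(cfg) {
  probs <- c(cfg$lectin_block_bias, cfg$fraction_ks_above_threshold,
             cfg$signal_peptide_rate, cfg$tm_rate, cfg$family_proportions)
  if (any(probs < 0 | probs > 1)) {
    rlang::abort("config error: probabilities must lie in [0, 1]")
  }
  if (abs(sum(cfg$family_proportions) - 1) > 1e-8) {
    rlang::abort("config error: family_proportions must sum to 1")
  }
  if (!all(names(cfg$family_proportions) %in% lectin_family_names())) {
    rlang::abort("config error: unknown family in family_proportions")
  }
  for (r in list(cfg$tandem_array_size_range, cfg$tandem_spacing_range,
                 cfg$block_size_range)) {
    if (length(r) != 2L || r[1] > r[2] || r[1] < 0L) {
      rlang::abort("config error: ranges must be (min, max) with 0 <= min <= max")
    }
  }
  if (cfg$tandem_array_size_range[1] < 2L) {
    rlang::abort("config error: tandem arrays need at least 2 members")
  }
  max_span <- (cfg$tandem_array_size_range[2] - 1L) *
    (cfg$tandem_spacing_range[2] + 1L) + 1L
  if (max_span > cfg$genes_per_chromosome) {
    rlang::abort("config error: tandem array span exceeds chromosome length")
  }
  if (cfg$block_size_range[2] > cfg$genes_per_chromosome %/% 2L) {
    rlang::abort("config error: collinear block longer than half a chromosome")
  }
  invisible(cfg)
}

# draw n values from a candidate vector, safe for length-1 vectors (base
# sample() would treat a scalar as 1:x)
.draw_from <- function(v, n = 1L) {
  v[sample.int(length(v), n, replace = TRUE)]
}

# architecture templates per family, drawn from the chimerolectin catalogue:
# lectin+kinase receptors (LecRLKs), F-box lectins, glycoside-hydrolase
# fusions, tandem-arrayed lectin units, and plain (signal-peptide) lectins
.family_templates <- function() {
  list(
    "CRA" = list(c("SP", "CRA"), c("SP", "CRA", "TM", "kinase")),
    "EUL" = list("EUL"),
    "GNA" = list(c("SP", "GNA"),
                 c("SP", "GNA", "Slocus", "PAN", "TM", "kinase"),
                 c("SP", "GNA", "TM", "kinase"),
                 c("SP", "thaumatin", "GNA", "TM", "kinase"),
                 c("SP", "GNA", "Slocus", "PAN", "TIR", "NB-ARC", "LRR", "LRR", "LRR")),
    "hevein" = list(c("SP", "hevein", "Barwin"), c("SP", "hevein", "chitinase")),
    "jacalin" = list("jacalin", c("F-box", "jacalin"),
                     c("jacalin", "jacalin", "jacalin")),
    "legume" = list(c("SP", "legume"), c("SP", "legume", "TM", "kinase"),
                    c("legume", "legume"), c("RT", "legume", "TM", "kinase")),
    "LysM" = list(c("SP", "LysM"), c("SP", "LysM", "TM", "kinase"),
                  c("LysM", "LysM"), c("F-box", "LysM"), c("EEIG1", "LysM")),
    "Nictaba" = list("Nictaba", c("F-box", "Nictaba"), c("Nictaba", "Nictaba")),
    "ricin B" = list(c("SP", "GH5", "ricin B"), c("SP", "GH27", "ricin B"))
  )
}

#' Simulate annotation inputs with planted duplication structure
#'
#' Generates, deterministically for a given config (including its seed),
#' the four inputs of the expansion pipeline -- gene annotation, domain-hit
#' table, signal-peptide/TM topology table, and a collinearity file with
#' per-pair Ks -- together with truth labels for every planted structure.
#'
#' Planted tandem arrays respect the configured member spacing, and all
#' planted same-family lectin genes on a chromosome are separated by more
#' than the tandem window unless they belong to the same array, so the
#' arrays are exactly the tandem clusters detectable at
#' `max_intervening`. Collinear pair Ks values are drawn from the
#' recent/ancient lognormal mixture with the ancient (saturated, Ks >
#' `ks_max`) component chosen with probability
#' `fraction_ks_above_threshold`, so the planted saturated fraction is
#' exactly binomial. Truth mechanism labels are derived from the planted
#' structures alone: tandem = array membership, segmental = incidence in a
#' pair with Ks <= `ks_max`.
#'
#' @param config a `simulation_config`.
#' @return list of class `lectin_simulation` with elements `genes`,
#'   `domain_hits`, `topology`, `collinearity` (tibbles), `truth` (list:
#'   `genes` with per-gene family/architecture/mechanism, `arrays`,
#'   `pairs`), and `config`. Use [write_simulation()] to materialise the
#'   four input files.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  .validate_config(config)
  set.seed(config$seed)
  defs <- lectin_family_definitions()
  fams <- names(config$family_proportions)
  n <- config$genes_per_chromosome
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  margin <- config$max_intervening + 2L  # index distance that cannot link

  # background gene scaffold; starts strictly increasing per chromosome
  gene_tabs <- lapply(seq_along(chroms), function(ci) {
    starts <- cumsum(sample(2000:20000, n, replace = TRUE))
    len <- sample(500:5000, n, replace = TRUE)
    tibble::tibble(
      gene_id = sprintf("Gm%02dg%05d", ci, seq_len(n) * 10L),
      chromosome = chroms[ci],
      start = starts,
      end = starts + len,
      strand = sample(c("+", "-"), n, replace = TRUE)
    )
  })

  # family label per (chromosome, index); NA = background
  fam_at <- matrix(NA_character_, nrow = config$n_chromosomes, ncol = n)

  .isolated <- function(ci, idxs, fam) {
    if (any(!is.na(fam_at[ci, idxs]))) return(FALSE)
    same <- which(!is.na(fam_at[ci, ]) & fam_at[ci, ] == fam)
    if (length(same) == 0L) return(TRUE)
    all(abs(outer(idxs, same, "-")) >= margin)
  }

  arrays <- list()
  if (config$n_tandem_arrays > 0L) {
    for (a in seq_len(config$n_tandem_arrays)) {
      fam <- sample(fams, 1L, prob = config$family_proportions)
      size <- .draw_from(seq(config$tandem_array_size_range[1],
                             config$tandem_array_size_range[2]))
      spacing <- .draw_from(seq(config$tandem_spacing_range[1],
                                config$tandem_spacing_range[2]), size - 1L)
      offsets <- cumsum(c(0L, spacing + 1L))
      placed <- FALSE
      for (try in seq_len(500L)) {
        ci <- sample(config$n_chromosomes, 1L)
        first <- sample(seq_len(n - offsets[size]), 1L)
        idxs <- first + offsets
        if (.isolated(ci, idxs, fam)) {
          fam_at[ci, idxs] <- fam
          arrays[[a]] <- tibble::tibble(
            array_id = sprintf("array_%02d", a),
            family = fam,
            chromosome = chroms[ci],
            members = list(gene_tabs[[ci]]$gene_id[idxs]),
            spacings = list(spacing)
          )
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        rlang::abort("config error: could not place a tandem array; genome too dense")
      }
    }
  }
  arrays <- if (length(arrays) > 0L) dplyr::bind_rows(arrays) else tibble::tibble(
    array_id = character(), family = character(), chromosome = character(),
    members = list(), spacings = list()
  )

  if (config$n_scattered_lectins > 0L) {
    for (s in seq_len(config$n_scattered_lectins)) {
      for (try in seq_len(500L)) {
        fam <- sample(fams, 1L, prob = config$family_proportions)
        ci <- sample(config$n_chromosomes, 1L)
        idx <- sample(n, 1L)
        if (.isolated(ci, idx, fam)) {
          fam_at[ci, idx] <- fam
          break
        }
        if (try == 500L) {
          rlang::abort("config error: could not place scattered lectin genes")
        }
      }
    }
  }

  genes <- dplyr::bind_rows(gene_tabs)
  fam_by_gene <- stats::setNames(
    as.vector(t(fam_at)),
    unlist(lapply(gene_tabs, function(g) g$gene_id))
  )
  fam_by_gene <- fam_by_gene[!is.na(fam_by_gene)]

  # unmapped-scaffold lectin genes (retained in totals, never tandem)
  if (config$n_scaffold_genes > 0L) {
    sc_fams <- sample(fams, config$n_scaffold_genes, replace = TRUE,
                      prob = config$family_proportions)
    sc <- tibble::tibble(
      gene_id = sprintf("GmU%05d", seq_len(config$n_scaffold_genes) * 10L),
      chromosome = sprintf("scaffold_%04d", seq_len(config$n_scaffold_genes)),
      start = sample(1000:50000, config$n_scaffold_genes, replace = TRUE),
      end = NA_integer_,
      strand = sample(c("+", "-"), config$n_scaffold_genes, replace = TRUE)
    )
    sc$end <- sc$start + sample(500:5000, config$n_scaffold_genes, replace = TRUE)
    genes <- dplyr::bind_rows(genes, sc)
    fam_by_gene <- c(fam_by_gene, stats::setNames(sc_fams, sc$gene_id))
  }

  # collinear blocks: runs of consecutive genes paired between two regions
  pairs <- list()
  lectin_positions <- which(!is.na(fam_at), arr.ind = TRUE)
  if (config$n_collinear_blocks > 0L) {
    for (b in seq_len(config$n_collinear_blocks)) {
      k <- .draw_from(seq(config$block_size_range[1], config$block_size_range[2]))
      if (nrow(lectin_positions) > 0L &&
          stats::runif(1) < config$lectin_block_bias) {
        pick <- lectin_positions[sample(nrow(lectin_positions), 1L), ]
        ci_a <- pick[["row"]]
        anchor <- pick[["col"]]
        first_a <- min(max(1L, anchor - .draw_from(0:(k - 1L))), n - k + 1L)
      } else {
        ci_a <- sample(config$n_chromosomes, 1L)
        first_a <- sample(n - k + 1L, 1L)
      }
      repeat {
        ci_b <- sample(config$n_chromosomes, 1L)
        first_b <- sample(n - k + 1L, 1L)
        if (ci_b != ci_a || abs(first_b - first_a) >= k) break
      }
      ancient <- stats::runif(k) < config$fraction_ks_above_threshold
      ks <- vapply(ancient, function(anc) {
        .draw_ks(config$ks_distribution, anc, config$ks_max)
      }, numeric(1))
      pairs[[b]] <- tibble::tibble(
        block_id = as.character(b - 1L),
        gene_a = gene_tabs[[ci_a]]$gene_id[first_a + seq_len(k) - 1L],
        gene_b = gene_tabs[[ci_b]]$gene_id[first_b + seq_len(k) - 1L],
        ks = round(ks, 4)
      )
    }
  }
  pairs <- if (length(pairs) > 0L) dplyr::bind_rows(pairs) else tibble::tibble(
    block_id = character(), gene_a = character(), gene_b = character(),
    ks = numeric()
  )

  # domain hits and topology from architecture templates
  templates <- .family_templates()
  arch_by_gene <- character(0)
  hit_rows <- list()
  topo_rows <- list()
  vocab_acc <- stats::setNames(defs$tokens$accession, defs$tokens$token)
  vocab_len <- stats::setNames(defs$tokens$length, defs$tokens$token)
  fam_acc <- stats::setNames(
    vapply(defs$families$accessions, `[[`, character(1), 1),
    defs$families$family
  )
  fam_len <- stats::setNames(defs$families$reference_domain_length,
                             defs$families$family)

  for (gid in names(fam_by_gene)) {
    fam <- fam_by_gene[[gid]]
    tmpl <- templates[[fam]][[sample(length(templates[[fam]]), 1L)]]
    arch_by_gene[[gid]] <- architecture_string(tmpl)
    pos <- if (tmpl[1] == "SP") 31L else 1L
    has_sp <- tmpl[1] == "SP"
    tms <- NULL
    for (tok in tmpl) {
      if (tok == "SP") next
      if (tok == "TM") {
        tms <- rbind(tms, c(pos, pos + 20L))
        pos <- pos + 21L + 10L
        next
      }
      if (tok %in% names(fam_acc)) {
        acc <- fam_acc[[tok]]
        len <- fam_len[[tok]]
        desc <- paste0(tok, " lectin domain")
      } else {
        acc <- vocab_acc[[tok]]
        len <- vocab_len[[tok]]
        desc <- paste0(tok, " domain")
      }
      hit_rows[[length(hit_rows) + 1L]] <- tibble::tibble(
        protein_id = gid, domain_accession = acc, description = desc,
        d_start = pos, d_end = pos + len - 1L,
        score = 10^(-stats::runif(1, 10, 50))
      )
      pos <- pos + len + 10L
    }
    topo_rows[[length(topo_rows) + 1L]] <- tibble::tibble(
      protein_id = gid, has_signal_peptide = has_sp,
      tm_segments = list(if (is.null(tms)) {
        matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
      } else {
        dimnames(tms) <- list(NULL, c("start", "end")); tms
      })
    )
  }

  # background proteins: occasional non-lectin domains, SP/TM annotations
  bg_ids <- setdiff(genes$gene_id, names(fam_by_gene))
  bg_dom <- bg_ids[stats::runif(length(bg_ids)) < 0.2]
  if (length(bg_dom) > 0L) {
    tok <- sample(defs$tokens$token, length(bg_dom), replace = TRUE)
    hit_rows[[length(hit_rows) + 1L]] <- tibble::tibble(
      protein_id = bg_dom,
      domain_accession = unname(vocab_acc[tok]),
      description = paste0(tok, " domain"),
      d_start = 20L,
      d_end = 20L + unname(vocab_len[tok]) - 1L,
      score = 10^(-stats::runif(length(bg_dom), 10, 50))
    )
  }
  bg_sp <- stats::runif(length(bg_ids)) < config$signal_peptide_rate
  bg_tm <- stats::runif(length(bg_ids)) < config$tm_rate
  topo_rows[[length(topo_rows) + 1L]] <- tibble::tibble(
    protein_id = bg_ids,
    has_signal_peptide = bg_sp,
    tm_segments = lapply(bg_tm, function(has) {
      if (has) {
        matrix(c(200L, 220L), ncol = 2, dimnames = list(NULL, c("start", "end")))
      } else {
        matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
      }
    })
  )

  domain_hits <- dplyr::arrange(dplyr::bind_rows(hit_rows),
                                .data$protein_id, .data$d_start)
  topology <- dplyr::arrange(dplyr::bind_rows(topo_rows), .data$protein_id)

  # truth labels from the planted structures alone
  tandem_truth <- unique(unlist(arrays$members))
  retained <- pairs[pairs$ks <= config$ks_max, , drop = FALSE]
  segmental_truth <- intersect(unique(c(retained$gene_a, retained$gene_b)),
                               names(fam_by_gene))
  mech <- ifelse(names(fam_by_gene) %in% tandem_truth,
                 ifelse(names(fam_by_gene) %in% segmental_truth, "both", "tandem_only"),
                 ifelse(names(fam_by_gene) %in% segmental_truth,
                        "segmental_only", "other"))
  truth_genes <- tibble::tibble(
    gene_id = names(fam_by_gene),
    family = unname(fam_by_gene),
    architecture = unname(arch_by_gene[names(fam_by_gene)]),
    mechanism = mech
  )
  truth_genes <- dplyr::arrange(truth_genes, .data$gene_id)

  structure(list(
    genes = genes,
    domain_hits = domain_hits,
    topology = topology,
    collinearity = pairs,
    truth = list(genes = truth_genes, arrays = arrays, pairs = pairs),
    config = config
  ), class = "lectin_simulation")
}

# one Ks draw from the mixture component, truncated to its side of ks_max
.draw_ks <- function(dist, ancient, ks_max) {
  i <- if (ancient) 2L else 1L
  for (try in seq_len(10000L)) {
    x <- stats::rlnorm(1, dist$meanlog[i], dist$sdlog[i])
    if (ancient && x > ks_max) return(x)
    if (!ancient && x <= ks_max) return(x)
  }
  rlang::abort("config error: Ks mixture component cannot reach its side of ks_max")
}

#' Write simulated inputs to disk
#'
#' Materialises a simulation as the four pipeline input files plus a truth
#' table: `genes.gff3`, `domains.tsv`, `topology.tsv`, `collinearity.txt`,
#' `truth_genes.tsv`. Output is byte-identical for identical simulations.
#'
#' @param sim a `lectin_simulation` from [simulate_genome()].
#' @param dir output directory (created if missing).
#' @return named character vector of the five file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "lectin_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    gff3 = file.path(dir, "genes.gff3"),
    domains = file.path(dir, "domains.tsv"),
    topology = file.path(dir, "topology.tsv"),
    collinearity = file.path(dir, "collinearity.txt"),
    truth = file.path(dir, "truth_genes.tsv")
  )
  g <- sim$genes
  writeLines(c(
    "##gff-version 3",
    sprintf("%s\tlectinscape_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            g$chromosome, g$start, g$end, g$strand, g$gene_id)
  ), paths[["gff3"]])

  write_table(sim$domain_hits, paths[["domains"]],
              schema = c("protein_id", "domain_accession", "description",
                         "d_start", "d_end", "score"))

  topo <- tibble::tibble(
    protein_id = sim$topology$protein_id,
    signal_peptide = sim$topology$has_signal_peptide,
    tm_segments = vapply(sim$topology$tm_segments, function(m) {
      if (nrow(m) == 0L) "" else paste(paste0(m[, 1], "-", m[, 2]), collapse = ";")
    }, character(1))
  )
  readr::write_tsv(topo, paths[["topology"]], na = "NA", progress = FALSE)

  lines <- character(0)
  if (nrow(sim$collinearity) > 0L) {
    for (b in unique(sim$collinearity$block_id)) {
      bp <- sim$collinearity[sim$collinearity$block_id == b, , drop = FALSE]
      lines <- c(lines,
                 sprintf("## Alignment %s: score=%d e_value=0 N=%d plus",
                         b, 100L * nrow(bp), nrow(bp)),
                 sprintf("%3s-%3d:\t%s\t%s\t%s", b, seq_len(nrow(bp)) - 1L,
                         bp$gene_a, bp$gene_b,
                         ifelse(is.na(bp$ks), "NA", sprintf("%.4f", bp$ks))))
    }
  }
  writeLines(lines, paths[["collinearity"]])

  write_table(sim$truth$genes, paths[["truth"]])
  invisible(paths)
}

#' Per-family lectin gene counts from the published soybean survey
#'
#' The printed per-family predicted gene counts, percentages and
#' chromosome-localisation strings for the soybean genome: nine non-empty
#' families (CRA 6, EUL 3, GNA 166, hevein 6, jacalin 5, legume 94, LysM
#' 47, Nictaba 22, ricin B 10) and three absent ones (ABA, amaranthin,
#' cyanovirin), 359 genes in total. Used as a worked input for the
#' summary arithmetic.
#'
#' @return tibble `family`, `n_genes`, `percentage` (as printed),
#'   `chromosomes`.
#' @export
table1_fixture <- function() {
  tibble::tibble(
    family = lectin_family_names(),
    n_genes = c(0L, 0L, 6L, 0L, 3L, 166L, 6L, 5L, 94L, 47L, 22L, 10L),
    percentage = c(0.0, 0.0, 1.7, 0.0, 0.8, 46.2, 1.7, 1.4, 26.2, 13.1, 6.1, 2.8),
    chromosomes = c("/", "/", "13, 15, 17", "/", "16, 19", "all except chr 5",
                    "2, 12, 13, 16, 19", "2, 11, 13, 15, 18",
                    "all except chr 4 and chr 19", "all except chr 12",
                    "3, 5, 6, 7, 10, 14, 17, 19, 20", "5, 8, 11, 18")
  )
}

#' Per-family tandem and segmental duplication counts from the survey
#'
#' The printed per-family duplication summary for the nine non-empty
#' soybean lectin families: number of tandem duplication clusters, genes
#' involved in tandem duplication, and genes involved in segmental
#' duplication.
#'
#' @return tibble `family`, `n_genes`, `tandem_clusters`, `tandem_genes`,
#'   `segmental_genes`.
#' @export
table3_fixture <- function() {
  tibble::tibble(
    family = c("CRA", "EUL", "GNA", "hevein", "jacalin", "legume",
               "LysM", "Nictaba", "ricin B"),
    n_genes = c(6L, 3L, 166L, 6L, 5L, 94L, 47L, 22L, 10L),
    tandem_clusters = c(0L, 1L, 26L, 1L, 0L, 16L, 2L, 5L, 2L),
    tandem_genes = c(0L, 2L, 114L, 2L, 0L, 49L, 4L, 13L, 4L),
    segmental_genes = c(4L, 0L, 69L, 3L, 5L, 51L, 38L, 11L, 7L)
  )
}
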