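#' Build an aligned character matrix for parsimony analysis
#'
#' @param sequences named character vector of equal-length aligned
#'   sequences (amino acids plus `-` for gaps), or a character matrix with
#'   taxa as rownames.
#' @return character matrix (taxa x sites, uppercase) of class
#'   `character_matrix`.
#' @export
character_matrix <- function(sequences) {
  if (is.matrix(sequences)) {
    m <- toupper(sequences)
  } else {
    if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
      rlang::abort("sequences must have unique names")
    }
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1L) {
      rlang::abort("aligned sequences must all have the same length")
    }
    m <- do.call(rbind, strsplit(toupper(sequences), ""))
    rownames(m) <- names(sequences)
  }
  if (nrow(m) < 3L) {
    rlang::abort("a character matrix needs at least 3 taxa")
  }
  class(m) <- c("character_matrix", class(m))
  m
}

#' Read an aligned FASTA file into a character matrix
#'
#' @param path path to an aligned FASTA file (amino acids).
#' @return a `character_matrix`.
#' @export
read_alignment <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  character_matrix(stats::setNames(toupper(unlist(seqs)), names(seqs)))
}

# encode tip states as per-site integer bitmasks over the matrix alphabet;
# with gap_as_state = FALSE, "-" means "any state" (all bits set)
.tip_masks <- function(mat, gap_as_state = TRUE) {
  alphabet <- sort(unique(as.vector(mat)))
  if (!gap_as_state && "-" %in% alphabet) {
    alphabet <- setdiff(alphabet, "-")
  }
  if (length(alphabet) > 30L) {
    rlang::abort("alphabet too large for bitmask encoding (> 30 states)")
  }
  bit <- stats::setNames(bitwShiftL(1L, seq_along(alphabet) - 1L), alphabet)
  all_bits <- Reduce(bitwOr, bit)
  masks <- matrix(0L, nrow = nrow(mat), ncol = ncol(mat),
                  dimnames = list(rownames(mat), NULL))
  for (i in seq_len(nrow(mat))) {
    v <- mat[i, ]
    m <- unname(bit[v])
    if (!gap_as_state) m[v == "-"] <- all_bits
    masks[i, ] <- m
  }
  masks
}

# Fitch pass over an edge list (2-column matrix of node labels), rooted at
# `root`; tips carry bitmask rows in `masks`. Returns total state changes.
# Internal nodes combine their children pairwise in sequence, which is exact
# for binary trees stored with at most a trifurcating root.
.fitch_edges <- function(edges, masks, root) {
  adj <- split(c(edges[, 1], edges[, 2]), c(edges[, 2], edges[, 1]))
  n_sites <- ncol(masks)
  changes <- 0L
  rec <- function(node, parent) {
    kids <- setdiff(adj[[node]], parent)
    if (length(kids) == 0L) {
      return(masks[node, ])
    }
    acc <- rec(kids[1], node)
    for (k in kids[-1]) {
      km <- rec(k, node)
      inter <- bitwAnd(acc, km)
      disjoint <- inter == 0L
      changes <<- changes + sum(disjoint)
      acc <- ifelse(disjoint, bitwOr(acc, km), inter)
    }
    acc
  }
  # root at a tip's neighbour so the recursion covers every edge once
  invisible(rec(root, NA_character_))
  changes
}

#' Fitch parsimony score of a tree
#'
#' The minimum total number of character-state changes over all sites,
#' computed by the Fitch small-parsimony pass. The score is a property of
#' the unrooted topology: it is invariant under re-rooting and leaf-order
#' permutation. Gaps are treated as an ordinary 21st state by default;
#' with `gap_as_state = FALSE` a gap is treated as missing data (compatible
#' with every state).
#'
#' @param tree an `ape::phylo` tree (rooted or unrooted, binary).
#' @param mat a `character_matrix` whose taxa equal the tree's tip labels.
#' @param gap_as_state logical; see Details.
#' @return integer parsimony score.
#' @export
fitch_score <- function(tree, mat, gap_as_state = TRUE) {
  if (!setequal(tree$tip.label, rownames(mat))) {
    rlang::abort("tree taxa and matrix taxa differ")
  }
  masks <- .tip_masks(mat, gap_as_state)
  n_tip <- length(tree$tip.label)
  lab <- c(tree$tip.label, paste0(".n", seq_len(tree$Nnode)))
  edges <- cbind(lab[tree$edge[, 1]], lab[tree$edge[, 2]])
  root <- lab[n_tip + 1L]
  .fitch_edges(edges, masks, root)
}

# --- branch-and-bound over unrooted binary topologies -----------------------

# canonical newick for an edge list: root at the internal node adjacent to
# the lexicographically smallest taxon, sort children by smallest descendant
.canonical_newick <- function(edges, taxa) {
  adj <- split(c(edges[, 1], edges[, 2]), c(edges[, 2], edges[, 1]))
  anchor <- sort(taxa)[1]
  root <- adj[[anchor]][1]
  build <- function(node, parent) {
    kids <- setdiff(adj[[node]], parent)
    if (length(kids) == 0L) {
      return(list(str = node, min = node))
    }
    sub <- lapply(kids, build, parent = node)
    ord <- order(vapply(sub, `[[`, character(1), "min"))
    sub <- sub[ord]
    list(
      str = paste0("(", paste(vapply(sub, `[[`, character(1), "str"),
                              collapse = ","), ")"),
      min = sub[[1]]$min
    )
  }
  sub <- build(root, anchor)
  paste0("(", anchor, ",", substr(sub$str, 2, nchar(sub$str) - 1), ");")
}

#' Exact maximum-parsimony tree search by branch and bound
#'
#' Finds the globally most parsimonious unrooted binary topology (or
#' topologies, when tied) for an aligned character matrix, by stepwise
#' taxon addition in input order with a max-mini style bound: a partial
#' tree is abandoned when its Fitch score plus a per-site lower bound --
#' one guaranteed change for every state present among the unadded taxa
#' but absent from the partial tree at that site -- already exceeds the
#' best complete score found. The search is exhaustive up to pruning, so
#' the returned score is the global optimum and the tree set contains
#' every optimal topology.
#'
#' @param mat a `character_matrix`.
#' @param gap_as_state treat gaps as a 21st state (default) or as missing.
#' @param max_taxa refuse matrices with more taxa than this; the number of
#'   unrooted topologies grows as (2n-5)!!, so beyond ~15 taxa an exact
#'   search is impractical and a heuristic tool should be used instead.
#' @return list with `score` (integer), `trees` (`ape::multiPhylo` of all
#'   optimal topologies), and `newick` (their canonical newick strings,
#'   sorted).
#' @export
branch_and_bound_search <- function(mat, gap_as_state = TRUE, max_taxa = 15L) {
  taxa <- rownames(mat)
  n <- length(taxa)
  if (n > max_taxa) {
    rlang::abort(paste0(
      "matrix has ", n, " taxa; exact branch-and-bound is limited to ",
      max_taxa, ". Use a heuristic search tool for larger problems."
    ))
  }
  masks <- .tip_masks(mat, gap_as_state)

  # per-site OR of masks for taxa not yet added, for the lower bound
  suffix_or <- matrix(0L, nrow = n + 1L, ncol = ncol(masks))
  for (i in seq(n, 1L)) {
    suffix_or[i, ] <- bitwOr(suffix_or[i + 1L, ], masks[taxa[i], ])
  }

  start_edges <- cbind(".i1", taxa[1:3])
  best <- list(score = .Machine$integer.max, trees = list())

  grow <- function(edges, next_taxon, n_internal) {
    added <- taxa[seq_len(next_taxon - 1L)]
    sc <- .fitch_edges(edges, masks, ".i1")
    if (next_taxon > n) {
      if (sc < best$score) {
        best <<- list(score = sc, trees = list(edges))
      } else if (sc == best$score) {
        best$trees[[length(best$trees) + 1L]] <<- edges
      }
      return(invisible())
    }
    present <- Reduce(bitwOr, lapply(added, function(t) masks[t, ]))
    lower <- sc + sum(.bit_count(bitwAnd(suffix_or[next_taxon, ], bitwNot(present))))
    if (lower > best$score) {
      return(invisible())
    }
    new_internal <- paste0(".i", n_internal + 1L)
    for (e in seq_len(nrow(edges))) {
      u <- edges[e, 1]; v <- edges[e, 2]
      new_edges <- rbind(edges[-e, , drop = FALSE],
                         c(u, new_internal),
                         c(new_internal, v),
                         c(new_internal, taxa[next_taxon]))
      grow(new_edges, next_taxon + 1L, n_internal + 1L)
    }
    invisible()
  }
  grow(start_edges, 4L, 1L)

  newick <- sort(vapply(best$trees, .canonical_newick, character(1), taxa = taxa))
  newick <- unique(newick)
  trees <- lapply(newick, function(s) ape::read.tree(text = s))
  class(trees) <- "multiPhylo"
  list(score = best$score, trees = trees, newick = newick)
}

# number of set bits per integer (small vectors, values < 2^30)
.bit_count <- function(x) {
  n <- integer(length(x))
  while (any(x > 0L)) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

#' Test whether a taxon set is monophyletic on an unrooted tree
#'
#' TRUE iff some edge of the tree induces a bipartition separating exactly
#' `taxa_subset` from the remaining taxa. A single taxon is always
#' monophyletic (its leaf edge).
#'
#' @param tree an `ape::phylo` tree.
#' @param taxa_subset nonempty proper subset of the tree's tip labels.
#' @return logical scalar.
#' @export
is_monophyletic <- function(tree, taxa_subset) {
  tips <- tree$tip.label
  unknown <- setdiff(taxa_subset, tips)
  if (length(unknown) > 0L) {
    rlang::abort(paste0("unknown taxon: ", .id_list(unknown)))
  }
  if (length(taxa_subset) == 0L || length(taxa_subset) >= length(tips)) {
    rlang::abort("taxa_subset must be a nonempty proper subset of the tree's taxa")
  }
  target <- sort(unique(taxa_subset))
  if (length(target) == 1L) return(TRUE)
  n_tip <- length(tips)
  tree <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) sets[[i]] <- tips[i]
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  for (e in seq_len(nrow(tree$edge))) {
    below <- sort(sets[[tree$edge[e, 2]]])
    if (identical(below, target) ||
        identical(sort(setdiff(tips, below)), target)) {
      return(TRUE)
    }
  }
  FALSE
}
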