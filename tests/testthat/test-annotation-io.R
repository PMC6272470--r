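gff_text <- function(rows) {
  c("##gff-version 3",
    vapply(rows, function(r) {
      sprintf("%s\tsrc\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              r$chr, r$start, r$end, r$strand %||% "+", r$id)
    }, character(1)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

write_gff <- function(rows) {
  path <- withr::local_tempfile(fileext = ".gff3", .local_envir = parent.frame())
  writeLines(gff_text(rows), path)
  path
}

test_that("gene ranks follow coordinates, not file order", {
  fwd <- write_gff(list(list(id = "A", chr = "chr1", start = 100L, end = 200L),
                        list(id = "B", chr = "chr1", start = 500L, end = 600L)))
  rev <- write_gff(list(list(id = "B", chr = "chr1", start = 500L, end = 600L),
                        list(id = "A", chr = "chr1", start = 100L, end = 200L)))
  g1 <- read_gene_annotation(fwd)
  g2 <- read_gene_annotation(rev)
  expect_equal(g1$rank[g1$gene_id == "A"], 0L)
  expect_equal(g1$rank[g1$gene_id == "B"], 1L)
  expect_equal(g1, g2)
})

test_that("ranks agree with a sort-then-enumerate oracle on random genomes", {
  set.seed(101)
  rows <- lapply(seq_len(50), function(i) {
    list(id = sprintf("g%02d", i),
         chr = sample(c("chr1", "chr2", "chr3"), 1),
         start = sample(1e6, 1), end = 0L)
  })
  rows <- lapply(rows, function(r) { r$end <- r$start + 400L; r })
  g <- read_gene_annotation(write_gff(rows))
  # oracle: plain order() per chromosome
  for (chr in unique(g$chromosome)) {
    sub <- g[g$chromosome == chr, ]
    expect_equal(sub$rank[order(sub$start)], seq_len(nrow(sub)) - 1L)
    expect_setequal(sub$rank, seq_len(nrow(sub)) - 1L)
  }
})

test_that("malformed coordinates and duplicate ids are rejected by id", {
  bad <- write_gff(list(list(id = "ok1", chr = "chr1", start = 10L, end = 20L),
                        list(id = "bad1", chr = "chr1", start = 50L, end = 30L)))
  expect_error(read_gene_annotation(bad), "bad1")
  dup <- write_gff(list(list(id = "X", chr = "chr1", start = 10L, end = 20L),
                        list(id = "X", chr = "chr2", start = 10L, end = 20L)))
  expect_error(read_gene_annotation(dup), "duplicate")
})

test_that("unmapped scaffolds are flagged unplaced but keep ranks", {
  g <- read_gene_annotation(write_gff(list(
    list(id = "A", chr = "chr1", start = 10L, end = 20L),
    list(id = "S", chr = "scaffold_17", start = 10L, end = 20L)
  )))
  expect_false(g$is_placed[g$gene_id == "S"])
  expect_true(g$is_placed[g$gene_id == "A"])
  expect_equal(g$rank[g$gene_id == "S"], 0L)
})

test_that("domain table drops unparseable coordinate rows with a count", {
  set.seed(7)
  n <- 200L
  tab <- tibble::tibble(
    protein_id = sprintf("P%03d", sample(50, n, replace = TRUE)),
    domain_accession = "PF01453",
    description = "test",
    d_start = as.character(sample(500, n, replace = TRUE)),
    d_end = NA_character_,
    score = "1e-30"
  )
  tab$d_end <- as.character(as.integer(tab$d_start) + 99L)
  corrupt <- sample(n, 10)
  tab$d_start[corrupt] <- "not_a_number"
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tab, path)
  expect_warning(hits <- read_domain_table(path), "10")
  expect_equal(nrow(hits), 190L)
  expect_false(is.unsorted(hits$protein_id))
})

test_that("domain hits come back sorted by start and missing columns error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tdomain_accession\tdescription\td_start\td_end\tscore",
               "P1\tPF01419\tjacalin\t300\t420\t1e-40",
               "P1\tPF01419\tjacalin\t10\t120\t1e-30"), path)
  hits <- read_domain_table(path)
  expect_equal(hits$d_start, c(10L, 300L))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\taccession", "P1\tPF1"), path2)
  expect_error(read_domain_table(path2), "mandatory")
})

test_that("topology reader suppresses N-terminal TM only alongside a signal peptide", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tsignal_peptide\ttm_segments",
               "P1\tTRUE\t5-25;200-220",
               "P2\tFALSE\t5-25",
               "P3\tTRUE\t25-45"), path)
  topo <- read_topology_table(path)
  expect_equal(unname(topo$tm_segments[[1]][, "start"]), 200L)
  expect_equal(nrow(topo$tm_segments[[2]]), 1L)   # no SP, keep N-terminal TM
  expect_equal(nrow(topo$tm_segments[[3]]), 1L)   # straddles the window, kept
})

test_that("collinearity parsing is block-scoped and orientation-free", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("## Alignment 0: score=500 N=3 plus",
               "0-0:\tA\tB\t0.5",
               "0-1:\tC\tD\t0.8",
               "0-2:\tE\tF\tNA",
               "## Alignment 1: score=100 N=2 plus",
               "1-0:\tA\tB\t0.6",
               "1-1:\tB\tA\t0.7"), path)
  pairs <- read_collinearity(path)
  expect_equal(nrow(pairs), 4L)   # (B,A) in block 1 duplicates (A,B)
  expect_equal(sum(pairs$block_id == "0"), 3L)
  expect_equal(sum(pairs$block_id == "1"), 1L)    # same pair in 2 blocks = 2 records
  expect_true(is.na(pairs$ks[pairs$gene_a == "E"]))
})

test_that("orientation duplicates within a block are removed", {
  set.seed(11)
  ga <- sprintf("L%02d", 1:40)
  gb <- sprintf("R%02d", 1:40)
  lines <- c("## Alignment 0: score=1 N=40 plus",
             sprintf("0-%d:\t%s\t%s\t%.3f", 0:39, ga, gb, runif(40)),
             sprintf("0-%d:\t%s\t%s\t%.3f", 40:43, gb[1:4], ga[1:4], runif(4)))
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(lines, path)
  expect_equal(nrow(read_collinearity(path)), 40L)
})

test_that("short pair lines are rejected with their line number", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("## Alignment 0: score=1 N=1 plus", "0-0:\tOnlyOneField"), path)
  expect_error(read_collinearity(path), "line 2")
})

test_that("tables round-trip losslessly through write/read", {
  set.seed(5)
  tab <- tibble::tibble(
    id = sprintf("g%03d", 1:100),
    family = sample(lectin_family_names(), 100, replace = TRUE),
    n = sample(0:50, 100, replace = TRUE),
    x = round(runif(100), 6)
  )
  tab$x[c(3, 50)] <- NA
  path <- withr::local_tempfile(fileext = ".tsv")
  write_table(tab, path)
  back <- read_table_tsv(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))
})

test_that("write_table honours schema order and writes header-only files", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_table(tibble::tibble(b = integer(), a = character()), path,
              schema = c("a", "b"))
  expect_equal(readLines(path), "a\tb")
  expect_error(write_table(tibble::tibble(a = 1), path, schema = c("a", "zz")),
               "zz")
})
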