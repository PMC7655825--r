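test_that("read 1 parsing follows the NN-S-NN-Q-NNNN layout", {
  p <- parse_read1(paste0("TT", "ACGTCAGT", "GA", "TGCATGCA", "AACG", "TT"))
  expect_equal(p$s_obs, "ACGTCAGT")
  expect_equal(p$q_obs, "TGCATGCA")
  expect_equal(p$umi_obs, "TTGAAACG")
  short <- parse_read1(strrep("A", 23))
  expect_true(all(is.na(short)))
  # vectorized with mixed validity
  v <- parse_read1(c(strrep("A", 23), paste0("CC", "ACGTCAGT", "GG",
                                             "TGCATGCA", "TTTT")))
  expect_true(is.na(v$s_obs[1]) && v$s_obs[2] == "ACGTCAGT")
})

test_that("barcode correction fixes exactly one substitution", {
  wl <- shared_design$s_set$sequences
  expect_equal(correct_barcode(wl[5], wl), wl[5])
  # every 1-substitution neighbor corrects back to its source
  for (b in wl[1:10]) {
    nb <- hamming1_neighbors(b)
    expect_true(all(correct_barcode(nb, wl) == b))
  }
  # two substitutions are rejected
  b <- wl[1]
  two <- paste0(ifelse(substr(b, 1, 1) == "A", "CC", "AA"), substr(b, 3, 8))
  expect_true(hamming(two, b) == 2)
  expect_true(is.na(correct_barcode(two, wl)))
  # N matches nothing
  expect_true(is.na(correct_barcode(paste0("NN", substr(b, 3, 8)), wl)))
  # correction never maps one whitelist barcode onto another
  expect_equal(correct_barcode(wl, wl), wl)
})

test_that("poly(A) trimming removes tracts of more than 7 A's", {
  r <- paste0(strrep("C", 32), strrep("A", 8))
  expect_equal(trim_polyA(r), strrep("C", 32))
  short <- paste0(strrep("C", 22), strrep("A", 8))
  expect_true(is.na(trim_polyA(short)))
  seven <- paste0(strrep("C", 20), strrep("A", 7), strrep("C", 10))
  expect_equal(trim_polyA(seven), seven)
  # trimming starts at the first qualifying tract
  mid <- paste0(strrep("G", 30), strrep("A", 9), strrep("G", 30))
  expect_equal(trim_polyA(mid), strrep("G", 30))
})

test_that("UMI collapse counts Hamming-1 connected components", {
  rec <- function(umis) data.frame(cell = "c", gene = "g", umi = umis)
  expect_equal(collapse_umis(rec(c("AAAAAAAA", "AAAAAAAT")))$molecules, 1)
  expect_equal(collapse_umis(rec(c("AAAAAAAA", "AAAAAATT")))$molecules, 2)
  # chain A-B-C with d(A,B) = d(B,C) = 1, d(A,C) = 2 joins one component
  expect_equal(collapse_umis(rec(c("AAAAAAAA", "AAAAAAAT", "AAAAAATT")))$molecules, 1)
  # duplicated reads of one molecule still count once
  expect_equal(collapse_umis(rec(rep("ACGTACGT", 5)))$molecules, 1)
})

test_that("component counting agrees with an igraph oracle", {
  skip_if_not_installed("igraph")
  set.seed(21)
  for (i in 1:30) {
    umis <- unique(vapply(1:sample(2:25, 1), function(j) {
      paste(sample(c("A", "C"), 8, replace = TRUE), collapse = "")
    }, character(1)))
    m <- length(umis)
    adj <- outer(seq_len(m), seq_len(m), Vectorize(function(a, b) {
      sum(strsplit(umis[a], "")[[1]] != strsplit(umis[b], "")[[1]]) == 1
    }))
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    expect_equal(scopekit:::count_umi_components(umis),
                 igraph::components(g)$no)
  }
})

test_that("species calls require a strict 90% majority", {
  m <- matrix(c(95, 5, 90, 10, 50, 50, 0, 0), ncol = 2, byrow = TRUE,
              dimnames = list(NULL, c("human", "mouse")))
  expect_equal(species_call(m), c("human", "mixed", "mixed", "unclassified"))
})

test_that("error-free reads reproduce the true molecule counts exactly", {
  sim <- simulate_expression(n_cells = 30, n_genes = 20,
                             mean_counts_per_gene = 2, malignant_frac = 0,
                             seed = 6)
  cells <- data.frame(
    cell_id = colnames(sim$counts),
    s = sample(shared_design$s_set$sequences, 30),
    q = sample(shared_design$q_set$sequences, 30)
  )
  reads <- simulate_reads(cells, sim$counts, gene_info = sim$gene_info,
                          error_rate = 0, polyA_rate = 0.5, seed = 7)
  res <- count_molecules(reads$r1, reads$r2, reads$tags,
                         shared_design$s_set$sequences,
                         shared_design$q_set$sequences)
  bc <- setNames(paste0(cells$s, cells$q), cells$cell_id)
  truth <- sim$counts[rowSums(sim$counts) > 0, colSums(sim$counts) > 0,
                      drop = FALSE]
  colnames(truth) <- unname(bc[colnames(truth)])
  got <- as.matrix(res$counts)[rownames(truth), colnames(truth)]
  expect_equal(got, truth)

  # molecule counts are invariant to read order and duplication
  ord <- sample(length(reads$r1))
  res2 <- count_molecules(reads$r1[ord], reads$r2[ord], reads$tags,
                          shared_design$s_set$sequences,
                          shared_design$q_set$sequences)
  expect_equal(res2$counts, res$counts)
  dup <- c(reads$r1, stats::setNames(reads$r1, paste0(names(reads$r1), "d")))
  dup2 <- c(reads$r2, stats::setNames(reads$r2, paste0(names(reads$r2), "d")))
  tags2 <- rbind(reads$tags,
                 transform(reads$tags, read_id = paste0(read_id, "d")))
  res3 <- count_molecules(dup, dup2, tags2,
                          shared_design$s_set$sequences,
                          shared_design$q_set$sequences)
  expect_equal(res3$counts, res$counts)
})

test_that("barcode rejection under substitution errors matches the binomial law", {
  sim <- simulate_expression(n_cells = 40, n_genes = 30,
                             mean_counts_per_gene = 3, malignant_frac = 0,
                             seed = 8)
  cells <- data.frame(
    cell_id = colnames(sim$counts),
    s = sample(shared_design$s_set$sequences, 40),
    q = sample(shared_design$q_set$sequences, 40)
  )
  err <- 0.02
  reads <- simulate_reads(cells, sim$counts, error_rate = err,
                          polyA_rate = 0, fragment_length = 40, seed = 9)
  res <- count_molecules(reads$r1, reads$r2, reads$tags,
                         shared_design$s_set$sequences,
                         shared_design$q_set$sequences)
  n <- res$summary$total_reads
  # a read survives iff each 8-nt barcode carries at most one substitution
  p_bc <- (1 - err)^8 + 8 * err * (1 - err)^7
  p_keep <- p_bc^2
  expect_equal(res$summary$dropped_short_read1, 0)
  expect_equal(res$summary$dropped_short_fragment, 0)
  kept <- res$summary$reads_kept
  expect_lt(abs(kept - n * p_keep), 3 * sqrt(n * p_keep * (1 - p_keep)) + 1)
})

test_that("count matrices round-trip through the MTX directory format", {
  sim <- simulate_expression(n_cells = 8, n_genes = 12,
                             mean_counts_per_gene = 3, seed = 3)
  res <- list(counts = methods::as(Matrix::Matrix(sim$counts, sparse = TRUE),
                                   "CsparseMatrix"),
              gene_info = sim$gene_info,
              summary = list(total_reads = 99))
  dir <- withr::local_tempdir()
  write_count_matrix(res, dir)
  back <- read_count_matrix(dir)
  expect_equal(as.matrix(back$counts), as.matrix(res$counts))
  expect_equal(back$gene_info$chromosome, res$gene_info$chromosome)
  expect_equal(back$summary$total_reads, 99)
})

test_that("regions are carried into suffixed cell barcodes", {
  cells <- data.frame(cell_id = c("c1", "c2"),
                      s = shared_design$s_set$sequences[1:2],
                      q = shared_design$q_set$sequences[1:2])
  counts <- matrix(c(3, 0, 0, 2), 2, dimnames = list(c("g1", "g2"), c("c1", "c2")))
  reads <- simulate_reads(cells, counts, error_rate = 0, polyA_rate = 0,
                          seed = 2)
  tags <- reads$tags
  tags$region <- ifelse(tags$gene == "g1", 1L, 2L)
  res <- count_molecules(reads$r1, reads$r2, tags,
                         shared_design$s_set$sequences,
                         shared_design$q_set$sequences)
  expect_true(all(grepl("-[12]$", colnames(res$counts))))
})
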