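test_that("per-cell ranks use ascending average ties and match a brute-force oracle", {
  # hand example: counts [5, 1, 1, 0] -> ranks [4, 2.5, 2.5, 1]
  m <- matrix(c(5, 1, 1, 0), 4, 1)
  expect_equal(unname(rank_within_cells(m)[, 1]), c(4, 2.5, 2.5, 1))

  # monotone-transform invariance: raw counts and logcounts agree per cell
  ac <- random_counts(12, 8, seed = 4, lambda = 3)
  counts <- as.matrix(SummarizedExperiment::assay(ac, "counts"))
  lc <- as.matrix(SummarizedExperiment::assay(normalize_logcounts(ac), "logcounts"))
  expect_equal(rank_within_cells(lc), rank_within_cells(counts),
               ignore_attr = TRUE)

  # 6 genes x 8 cells random fixture vs per-column brute-force ranks
  set.seed(8)
  x <- matrix(rpois(48, 2), 6, 8)
  got <- rank_within_cells(x)
  for (z in seq_len(8)) {
    expect_equal(unname(got[, z]), brute_rank(x[, z]))
  }

  expect_error(rank_within_cells(matrix(1, 1, 3)), "at least 2 genes")
})

test_that("per-cell-type deviation ranks follow the mean-rank comparison steps", {
  # single cell equal to its own mean: zero deviation everywhere, all tied
  m <- matrix(c(3, 2, 1), 3, 1)
  out <- celltype_rank_of_deviation(m, rank_within_cells(m), 1L)
  expect_equal(unname(out), rep(2, 3))

  # forced ordering: gene A deviates by 0, gene B by 1
  expr <- matrix(c(5, 1, 5, 3), 2, 2,
                 dimnames = list(c("A", "B"), c("c1", "c2")))
  # per-cell ranks: c1 = (2, 1), c2 = (2, 1); means (5, 2) -> mean ranks (2, 1)
  out2 <- celltype_rank_of_deviation(expr, rank_within_cells(expr), 1:2)
  expect_equal(unname(out2), c(1.5, 1.5)) # both deviate 0 here: ranks tie
  # construct real deviation: flip one cell's order
  expr3 <- matrix(c(5, 1, 1, 5, 5, 1), 2, 3,
                  dimnames = list(c("A", "B"), NULL))
  # means: A = 11/3, B = 7/3 -> mean ranks (2, 1); cell ranks: (2,1), (1,2), (2,1)
  # deviations: A = (0, 1, 0)/3, B = (0, 1, 0)/3 -> tie again; use asymmetric case
  expr4 <- matrix(c(5, 1, 4, 2, 1, 5), 2, 3)
  out4 <- celltype_rank_of_deviation(expr4, rank_within_cells(expr4), 1:3)
  # means: A = 10/3 > B = 8/3; mean ranks (2, 1)
  # cell ranks A: 2, 2, 1; dev A = (0 + 0 + 1)/3; dev B identical -> ties
  expect_equal(unname(out4), c(1.5, 1.5))

  # 5 genes x 10 cells vs the literal loop oracle
  set.seed(10)
  lm5 <- matrix(rlnorm(50), 5, 10)
  got <- celltype_rank_of_deviation(lm5, rank_within_cells(lm5), 1:10)
  expect_equal(unname(got), ri_oracle(lm5, rep("A", 10))$per_ct[1, ])

  expect_error(celltype_rank_of_deviation(lm5, rank_within_cells(lm5),
                                          integer(0)), "no cells")
})

test_that("rank invariance equals the eight-step loop oracle on random fixtures", {
  set.seed(123)
  for (rep_i in 1:25) {
    G <- sample(2:10, 1)
    n <- sample(6:50, 1)
    K <- sample(2:3, 1)
    types <- sample(LETTERS[1:K], n, replace = TRUE)
    # ensure every type appears
    types[seq_len(K)] <- LETTERS[1:K]
    mat <- matrix(rpois(G * n, 3) + rlnorm(G * n, 0, 0.1), G, n)
    got <- rank_invariance(mat, types)
    want <- ri_oracle(mat, types)
    expect_identical(unname(got$rank_invariance), want$rank_invariance)
    expect_identical(unname(got$rank_sum), want$rank_sum)
    expect_identical(unname(got$per_celltype_rank), want$per_ct)
  }
})

test_that("rank invariance values sum to N(N+1)/2 and are permutation invariant", {
  ac <- quiet(normalize_logcounts(random_counts(9, 40, types = c("A", "B", "C"),
                                                seed = 6, lambda = 4)))
  lc <- as.matrix(SummarizedExperiment::assay(ac, "logcounts"))
  types <- SummarizedExperiment::colData(ac)$cell_type
  res <- rank_invariance(lc, types)
  N <- nrow(lc)
  expect_equal(sum(res$rank_invariance), N * (N + 1) / 2)

  # permuting cells leaves the result unchanged
  set.seed(2)
  perm <- sample(ncol(lc))
  res_p <- rank_invariance(lc[, perm], types[perm])
  expect_identical(res$rank_invariance, res_p$rank_invariance)

  # relabeling cell types (same partition, new names) leaves values unchanged
  relab <- c(A = "Z", B = "Y", C = "X")[types]
  res_r <- rank_invariance(lc, relab)
  expect_identical(unname(res$rank_invariance), unname(res_r$rank_invariance))
})

test_that("step-vi ranks are stable when a cell is duplicated in a well-separated fixture", {
  # gene means far apart so duplication cannot reorder the mean-expression ranks
  set.seed(14)
  base <- 2^(0:5)
  mat <- matrix(rep(base, 12), 6, 12) * rlnorm(72, 0, 0.05)
  types <- rep(c("A", "B"), each = 6)
  r1 <- rank_invariance(mat, types)
  mat2 <- cbind(mat, mat[, 1])
  r2 <- rank_invariance(mat2, c(types, "A"))
  expect_identical(r1$per_celltype_rank["A", ], r2$per_celltype_rank["A", ])
})

test_that("planted constant-rank gene attains the top rank-invariance value", {
  # 20 genes x 300 cells, 3 cell types; gene 1 always holds the top rank
  set.seed(31)
  G <- 20; n <- 300
  types <- rep(c("A", "B", "C"), each = 100)
  mat <- matrix(rlnorm(G * n, 0, 1), G, n)
  mat[1, ] <- apply(mat, 2, max) + 1
  res <- rank_invariance(mat, types)
  expect_equal(unname(res$rank_invariance[1]), G)
  expect_identical(top_candidates(res, 1), res$gene_ids[1])
})

test_that("top_candidates sorts descending with stable ties and validates n", {
  res <- rank_invariance(matrix(c(1, 2, 3, 1, 2, 3), 3, 2,
                                dimnames = list(c("a", "b", "c"), NULL)),
                         c("A", "B"))
  expect_length(top_candidates(res, 3), 3L)
  expect_error(top_candidates(res, 4), "exceeds")
  expect_error(top_candidates(res, 0), "positive integer")
  # all three genes deviate zero -> all tied; stable order is input order
  expect_identical(top_candidates(res, 3), c("a", "b", "c"))
})

test_that("rank-invariance results serialize to TSV", {
  ac <- quiet(normalize_logcounts(random_counts(6, 20, seed = 13)))
  res <- rank_invariance(ac)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rank_invariance(res, path)
  back <- read.delim(path)
  expect_identical(back$gene_id, res$gene_ids)
  expect_equal(back$rank_invariance, unname(res$rank_invariance))
})
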