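test_that("expression filter keeps floor(fraction * G) top-mean genes, stable ties", {
  # forced ordering: means 1 < 2 < 3 < 4, keep the top half
  m <- matrix(rep(c(1L, 3L, 7L, 15L), 3), 4, 3,
              dimnames = list(paste0("g", 1:4), paste0("c", 1:3)))
  ac <- annotated_counts(m, data.frame(cell_type = rep("A", 3)))
  rep1 <- filter_top_expressed(ac, 0.5)
  expect_setequal(rep1$kept, c("g3", "g4"))

  # floor: 5 genes at fraction 0.5 keep 2
  ac5 <- random_counts(5, 6, seed = 11)
  expect_length(filter_top_expressed(ac5, 0.5)$kept, 2L)

  # all-tied means: stable boundary break keeps the first floor(f*G) genes
  mt <- matrix(2L, 4, 3, dimnames = list(paste0("g", 1:4), paste0("c", 1:3)))
  act <- annotated_counts(mt, data.frame(cell_type = rep("A", 3)))
  expect_identical(filter_top_expressed(act, 0.5)$kept, c("g1", "g2"))

  expect_error(filter_top_expressed(ac, 0), "\\(0, 1\\]")
  expect_error(filter_top_expressed(ac, 1.2), "\\(0, 1\\]")

  # monotone in fraction: larger fraction never shrinks the kept set
  k25 <- filter_top_expressed(ac5, 0.25)$kept
  k60 <- filter_top_expressed(ac5, 0.6)$kept
  expect_true(all(k25 %in% k60))
})

test_that("cell grouping collapses rare cell types across regions", {
  # 90 cells of one type split over 5 regions -> one collapsed group
  meta <- data.frame(
    cell_type = c(rep("Endo", 90), rep("Excit", 150)),
    region = c(rep(paste0("R", 1:5), 18), rep(c("R1", "R2"), 75)))
  m <- matrix(1L, 3, nrow(meta))
  ac <- annotated_counts(m, meta)
  grp <- build_groups(ac, rare_min = 100)
  endo <- grp$keys[grp$keys$cell_type == "Endo", ]
  expect_equal(nrow(endo), 1L)
  expect_equal(endo$region, "ALL")
  expect_equal(endo$n_cells, 90L)
  # Excit (150 cells) stays per-region
  expect_equal(sort(grp$keys$region[grp$keys$cell_type == "Excit"]),
               c("R1", "R2"))

  # boundary: exactly 100 cells collapses (<=), 101 does not
  meta2 <- data.frame(cell_type = rep("Micro", 101), region = "R1")
  grp2 <- build_groups(annotated_counts(matrix(1L, 2, 101), meta2), 100)
  expect_equal(grp2$keys$region, "R1")
  meta3 <- data.frame(cell_type = rep("Micro", 100), region = "R1")
  grp3 <- build_groups(annotated_counts(matrix(1L, 2, 100), meta3), 100)
  expect_equal(grp3$keys$region, "ALL")

  # no region metadata: one group per cell type
  meta4 <- data.frame(cell_type = rep(c("A", "B"), each = 120))
  grp4 <- build_groups(annotated_counts(matrix(1L, 2, 240), meta4), 100)
  expect_equal(grp4$keys$region, c("ALL", "ALL"))
  expect_equal(grp4$keys$cell_type, c("A", "B"))
})

test_that("proportion zero matches a dense double-loop oracle", {
  # direct counts
  m <- matrix(c(0L, 0L, 1L, 2L), 1, 4)
  ac <- annotated_counts(m, data.frame(cell_type = rep("A", 4)))
  pz <- compute_prop_zero(ac, build_groups(ac))
  expect_equal(unname(pz$pz[1, 1]), 0.5)

  # all-zero gene in a group has pz exactly 1
  m2 <- rbind(a = c(0L, 0L, 0L), b = c(1L, 0L, 2L))
  ac2 <- annotated_counts(m2, data.frame(cell_type = rep("A", 3)))
  pz2 <- compute_prop_zero(ac2, build_groups(ac2))
  expect_equal(unname(pz2$pz["a", 1]), 1)

  # random fixture vs explicit double loop over genes and groups
  ac3 <- random_counts(7, 30, types = c("A", "B", "C"), seed = 5, lambda = 1)
  grp <- build_groups(ac3, rare_min = 2)
  pz3 <- compute_prop_zero(ac3, grp)
  counts <- as.matrix(SummarizedExperiment::assay(ac3, "counts"))
  for (g in seq_along(grp$cells)) {
    for (i in seq_len(nrow(counts))) {
      n_zero <- 0
      for (z in grp$cells[[g]]) if (counts[i, z] == 0) n_zero <- n_zero + 1
      expect_equal(unname(pz3$pz[i, g]), n_zero / length(grp$cells[[g]]))
    }
  }
  expect_true(all(pz3$pz >= 0 & pz3$pz <= 1))
})

test_that("proportion-zero filter is strict at the cutoff and monotone in it", {
  pz <- structure(list(
    pz = matrix(c(0.2, 0.75, 0, 0, 0.9, 0.1), 3, 2, byrow = TRUE,
                dimnames = list(c("boundary", "clean", "bad"), c("A|ALL", "B|ALL"))),
    groups = data.frame(cell_type = c("A", "B"), region = "ALL",
                        n_cells = c(5L, 5L)),
    n_cells_per_group = c(5L, 5L)), class = "prop_zero_table")
  rep <- filter_prop_zero(pz, 0.75)
  expect_identical(rep$kept, "clean")      # 0.75 == cutoff is dropped (strict)
  expect_setequal(rep$dropped, c("boundary", "bad"))
  expect_error(filter_prop_zero(pz, 0), "\\(0, 1\\)")

  # raising the cutoff never shrinks the kept set
  k75 <- filter_prop_zero(pz, 0.75)$kept
  k95 <- filter_prop_zero(pz, 0.95)$kept
  expect_true(all(k75 %in% k95))
})

test_that("filters are invariant to cell permutation and compose in order", {
  ac <- random_counts(20, 40, types = c("A", "B"), seed = 9, lambda = 2)
  cfg <- run_config(pz_cutoff = 0.6, rare_group_min_cells = 3)
  res <- quiet(run_gene_filters(ac, cfg))

  set.seed(1)
  perm <- sample(ncol(ac))
  res_p <- quiet(run_gene_filters(ac[, perm], cfg))
  expect_identical(res$expression$kept, res_p$expression$kept)
  expect_identical(res$prop_zero$kept, res_p$prop_zero$kept)
  expect_equal(res$prop_zero_table$pz, res_p$prop_zero_table$pz)

  # composition: the prop-zero stage only sees expression-filter survivors
  expect_true(all(res$prop_zero$kept %in% res$expression$kept))
  expect_identical(rownames(res$prop_zero_table$pz), res$expression$kept)
  expect_identical(rownames(res$data), res$prop_zero$kept)
})

test_that("planted sparse gene is dropped while a dense gene survives", {
  # a POLR2A-like gene: zero in 90% of one group; a TREG-like gene: dense
  set.seed(21)
  n <- 60
  types <- rep(c("A", "B"), each = n / 2)
  polr2a <- ifelse(types == "A" & runif(n) < 0.9, 0L, 1L + rpois(n, 3))
  treg <- 5L + rpois(n, 5)
  filler <- matrix(rpois(3 * n, 4), 3, n,
                   dimnames = list(paste0("f", 1:3), NULL))
  m <- rbind(POLR2A = polr2a, TREG = treg, filler)
  ac <- annotated_counts(m, data.frame(cell_type = types))
  pz <- compute_prop_zero(ac, build_groups(ac, rare_min = 2))
  rep <- filter_prop_zero(pz, 0.75)
  expect_true("TREG" %in% rep$kept)
  expect_false("POLR2A" %in% rep$kept)
})

test_that("filter reports and PZ tables serialize to TSV", {
  ac <- random_counts(6, 12, seed = 2)
  rep <- filter_top_expressed(ac, 0.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_filter_report(rep, path)
  back <- read.delim(path)
  expect_setequal(back$gene_id[back$kept], rep$kept)

  pz <- compute_prop_zero(ac, build_groups(ac, rare_min = 2))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_prop_zero(pz, path2)
  back2 <- read.delim(path2, check.names = FALSE)
  expect_equal(as.matrix(back2[, -1]), pz$pz, ignore_attr = TRUE)
})
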