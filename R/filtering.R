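#' Keep the most highly expressed genes
#'
#' Ranks genes by mean expression across all cells (mean logcounts by
#' default, mean raw counts optionally) and keeps the top
#' `floor(fraction * G)`. High expression is required for detection by
#' smFISH probes, and low-expressed genes would flood the rank-invariance
#' step with low-value ties. Ties at the boundary are broken by input gene
#' order (stable).
#'
#' @param data a `SingleCellExperiment`; `logcounts` are computed on the
#'   fly if absent.
#' @param fraction fraction of genes to keep, in (0, 1].
#' @param metric `"logcounts"` (default) or `"counts"`.
#' @return a `gene_filter_report` with `kept`, `dropped`, `stage`,
#'   `threshold` fields.
#' @export
filter_top_expressed <- function(data, fraction = 0.5,
                                 metric = c("logcounts", "counts")) {
  metric <- match.arg(metric)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    treg_error("fraction must be a single value in (0, 1]")
  }
  if (nrow(data) < 2L) treg_error("need at least 2 genes")
  if (metric == "logcounts") {
    if (!"logcounts" %in% assayNames(data)) data <- normalize_logcounts(data)
    means <- rowMeans(assay(data, "logcounts"))
  } else {
    means <- rowMeans(assay(data, "counts"))
  }
  n_keep <- floor(fraction * nrow(data))
  ord <- order_desc_stable(means)
  kept_idx <- sort(ord[seq_len(n_keep)])
  genes <- rownames(data)
  gene_filter_report(kept = genes[kept_idx],
                     dropped = genes[setdiff(seq_along(genes), kept_idx)],
                     stage = "expression", threshold = fraction)
}

gene_filter_report <- function(kept, dropped, stage, threshold) {
  structure(list(kept = kept, dropped = dropped,
                 stage = stage, threshold = threshold),
            class = "gene_filter_report")
}

#' @export
print.gene_filter_report <- function(x, ...) {
  cat(sprintf("Gene filter report (%s stage, threshold %g)\n",
              x$stage, x$threshold))
  cat(sprintf("  kept %d genes, dropped %d\n",
              length(x$kept), length(x$dropped)))
  invisible(x)
}

#' Group cells by cell type and region, collapsing rare cell types
#'
#' Default groups are (cell_type, region) pairs. A cell type whose total
#' cell count across all regions is at most `rare_min` is collapsed into a
#' single region-ignorant group, flagged with the sentinel region `"ALL"` —
#' rare populations are too thin to support a per-region zero-proportion
#' estimate. When no region metadata is present every group is
#' (cell_type, "ALL"). Empty groups cannot arise (groups are built from the
#' cells present).
#'
#' @param data a `SingleCellExperiment` with `cell_type` (and optionally
#'   `region`) in `colData`.
#' @param rare_min collapse threshold on total cells per cell type.
#' @return a `treg_groups` object: a data.frame of `cell_type`, `region`,
#'   `n_cells` plus a list of cell index vectors.
#' @export
build_groups <- function(data, rare_min = 100) {
  ct <- as.character(colData(data)$cell_type)
  region <- colData(data)$region
  region <- if (is.null(region)) rep("NA", length(ct)) else as.character(region)
  region[is.na(region)] <- "NA"
  has_region <- any(region != "NA")
  type_totals <- table(ct)
  eff_region <- if (has_region) region else rep("ALL", length(ct))
  collapsed <- names(type_totals)[type_totals <= rare_min]
  eff_region[ct %in% collapsed] <- "ALL"
  key <- paste(ct, eff_region, sep = "|")
  idx <- split(seq_along(key), key)
  idx <- idx[order(names(idx))]
  parts <- strsplit(names(idx), "|", fixed = TRUE)
  structure(list(
    keys = data.frame(cell_type = vapply(parts, `[[`, "", 1L),
                      region = vapply(parts, `[[`, "", 2L),
                      n_cells = lengths(idx),
                      stringsAsFactors = FALSE),
    cells = unname(idx),
    labels = names(idx)
  ), class = "treg_groups")
}

#' @export
print.treg_groups <- function(x, ...) {
  cat(sprintf("%d cell groups\n", length(x$cells)))
  print(x$keys)
  invisible(x)
}

#' Proportion of zero counts per gene and group
#'
#' For every gene and every cell group, the fraction of cells in the group
#' with a zero count. A gene that cannot be observed in most cells of some
#' population is both a poor smFISH target and a source of rank ties.
#'
#' @param data a `SingleCellExperiment` with a `counts` assay.
#' @param groups a `treg_groups` object from [build_groups()].
#' @return a `prop_zero_table`: genes x groups matrix `pz` in \[0, 1\] plus
#'   the group table.
#' @export
compute_prop_zero <- function(data, groups) {
  stopifnot(is(groups, "treg_groups"))
  if (any(lengths(groups$cells) == 0L)) treg_error("empty cell group")
  counts <- assay(data, "counts")
  pz <- vapply(seq_along(groups$cells), function(g) {
    cells <- groups$cells[[g]]
    1 - rowSums(counts[, cells, drop = FALSE] > 0) / length(cells)
  }, numeric(nrow(counts)))
  pz <- matrix(pz, nrow = nrow(counts),
               dimnames = list(rownames(data), groups$labels))
  structure(list(pz = pz, groups = groups$keys,
                 n_cells_per_group = groups$keys$n_cells),
            class = "prop_zero_table")
}

#' @export
print.prop_zero_table <- function(x, ...) {
  cat(sprintf("Proportion-zero table: %d genes x %d groups\n",
              nrow(x$pz), ncol(x$pz)))
  invisible(x)
}

#' Drop genes with a high maximum proportion zero
#'
#' A gene is kept iff its maximum proportion zero across all groups is
#' strictly below `cutoff`; boundary genes are dropped.
#'
#' @param table a `prop_zero_table` from [compute_prop_zero()].
#' @param cutoff strict upper bound, in (0, 1).
#' @return a `gene_filter_report`.
#' @export
filter_prop_zero <- function(table, cutoff = 0.75) {
  stopifnot(is(table, "prop_zero_table"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L ||
      cutoff <= 0 || cutoff >= 1) {
    treg_error("cutoff must be a single value in (0, 1)")
  }
  max_pz <- apply(table$pz, 1L, max)
  genes <- rownames(table$pz)
  keep <- max_pz < cutoff
  gene_filter_report(kept = genes[keep], dropped = genes[!keep],
                     stage = "prop_zero", threshold = cutoff)
}

#' Run both gene filters in sequence
#'
#' Applies the expression filter, then the proportion-zero filter on the
#' survivors, logging the sizes of each stage.
#'
#' @param data a `SingleCellExperiment`.
#' @param config a [run_config()].
#' @return list with the filtered `data` (logcounts attached), the
#'   `expression` and `prop_zero` filter reports, and the `prop_zero_table`.
#' @export
run_gene_filters <- function(data, config = run_config()) {
  data <- normalize_logcounts(data)
  expr_report <- filter_top_expressed(data, config$top_expr_fraction)
  treg_log("INFO", "expression filter: kept %d of %d genes (fraction %g)",
           length(expr_report$kept), nrow(data), config$top_expr_fraction)
  data <- data[expr_report$kept, ]
  groups <- build_groups(data, config$rare_group_min_cells)
  pz <- compute_prop_zero(data, groups)
  pz_report <- filter_prop_zero(pz, config$pz_cutoff)
  treg_log("INFO", "proportion-zero filter: kept %d of %d genes (cutoff %g)",
           length(pz_report$kept), nrow(data), config$pz_cutoff)
  list(data = data[pz_report$kept, ],
       expression = expr_report,
       prop_zero_table = pz,
       prop_zero = pz_report)
}

#' Serialize a proportion-zero table to TSV
#'
#' One row per gene, one column per `cell_type|region` group.
#'
#' @param table a `prop_zero_table`.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_prop_zero <- function(table, path) {
  df <- data.frame(gene_id = rownames(table$pz), table$pz,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a gene filter report to TSV
#'
#' Columns `gene_id` and `kept` (TRUE/FALSE), every input gene present
#' exactly once.
#'
#' @param report a `gene_filter_report`.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_filter_report <- function(report, path) {
  df <- data.frame(gene_id = c(report$kept, report$dropped),
                   kept = rep(c(TRUE, FALSE),
                              c(length(report$kept), length(report$dropped))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
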