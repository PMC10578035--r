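#' Construct an annotated count matrix
#'
#' Bundles a sparse genes x cells matrix of raw UMI counts with per-cell
#' annotations into a [SingleCellExperiment::SingleCellExperiment], the
#' container every downstream stage consumes. Counts must be non-negative
#' integers; gene and cell identifiers must be unique; every cell needs a
#' non-empty `cell_type`. Optional metadata columns (`region`, `donor`,
#' `condition`) are filled with the sentinel `"NA"` when absent.
#'
#' @param counts genes x cells matrix (dense or sparse) of non-negative
#'   integer counts. Row and column names are used as gene / cell ids when
#'   `gene_ids` / `cell_ids` are not given.
#' @param cell_meta data.frame with one row per cell; must contain
#'   `cell_type`, may contain `region`, `donor`, `condition`.
#' @param gene_ids,cell_ids optional character vectors of identifiers.
#' @return a `SingleCellExperiment` with a `counts` assay.
#' @export
#' @examples
#' m <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = c(1, 2), dims = c(2, 2))
#' ac <- annotated_counts(m, data.frame(cell_type = c("Excit", "Oligo")),
#'                        gene_ids = c("g1", "g2"), cell_ids = c("c1", "c2"))
annotated_counts <- function(counts, cell_meta, gene_ids = rownames(counts),
                             cell_ids = colnames(counts)) {
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(ncol(counts)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(counts)) {
    treg_error("gene_ids length (%d) does not match matrix rows (%d)",
               length(gene_ids), nrow(counts))
  }
  if (length(cell_ids) != ncol(counts)) {
    treg_error("cell_ids length (%d) does not match matrix columns (%d)",
               length(cell_ids), ncol(counts))
  }
  if (anyDuplicated(gene_ids)) treg_error("duplicate gene ids")
  if (anyDuplicated(cell_ids)) treg_error("duplicate cell ids")
  if (length(counts@x) && any(counts@x < 0)) {
    treg_error("counts contain negative entries")
  }
  if (length(counts@x) && any(counts@x != round(counts@x))) {
    treg_error("counts contain non-integer entries")
  }
  cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
  if (nrow(cell_meta) != ncol(counts)) {
    treg_error("cell_meta rows (%d) do not match matrix columns (%d)",
               nrow(cell_meta), ncol(counts))
  }
  if (!"cell_type" %in% names(cell_meta)) {
    treg_error("cell_meta must contain a cell_type column")
  }
  ct <- as.character(cell_meta$cell_type)
  if (any(is.na(ct) | !nzchar(ct))) {
    treg_error("every cell needs a non-empty cell_type")
  }
  for (col in c("region", "donor", "condition")) {
    if (!col %in% names(cell_meta)) cell_meta[[col]] <- "NA"
    cell_meta[[col]] <- as.character(cell_meta[[col]])
    cell_meta[[col]][is.na(cell_meta[[col]])] <- "NA"
  }
  dimnames(counts) <- list(gene_ids, cell_ids)
  SingleCellExperiment(
    assays = list(counts = counts),
    rowData = DataFrame(gene_id = gene_ids, row.names = gene_ids),
    colData = DataFrame(cell_id = cell_ids,
                        cell_type = ct,
                        region = cell_meta$region,
                        donor = cell_meta$donor,
                        condition = cell_meta$condition,
                        row.names = cell_ids)
  )
}

#' Read an annotated count matrix from Matrix Market + TSV sidecars
#'
#' Reads a coordinate-format Matrix Market file together with a gene sidecar
#' (TSV with header containing a `gene_id` column) and a cell sidecar (TSV
#' with header containing `cell_id` and `cell_type`, optionally `region`,
#' `donor`, `condition`). Metadata columns are matched by header name, never
#' by position.
#'
#' @param matrix_path path to the `.mtx` file (genes on rows).
#' @param genes_path path to the gene TSV sidecar.
#' @param cells_path path to the cell TSV sidecar.
#' @return a `SingleCellExperiment`; see [annotated_counts()].
#' @export
read_counts <- function(matrix_path, genes_path, cells_path) {
  m <- readMM(matrix_path)
  genes <- read.delim(genes_path, stringsAsFactors = FALSE,
                      colClasses = "character")
  cells <- read.delim(cells_path, stringsAsFactors = FALSE,
                      colClasses = "character")
  if (!"gene_id" %in% names(genes)) {
    treg_error("%s: missing required column gene_id", genes_path)
  }
  for (col in c("cell_id", "cell_type")) {
    if (!col %in% names(cells)) {
      treg_error("%s: missing required column %s", cells_path, col)
    }
  }
  if (nrow(genes) != nrow(m)) {
    treg_error("%s: expected %d gene rows to match matrix %s, found %d",
               genes_path, nrow(m), matrix_path, nrow(genes))
  }
  if (nrow(cells) != ncol(m)) {
    treg_error("%s: expected %d cell rows to match matrix %s, found %d",
               cells_path, ncol(m), matrix_path, nrow(cells))
  }
  annotated_counts(m, cells, gene_ids = genes$gene_id, cell_ids = cells$cell_id)
}

#' Write an annotated count matrix to Matrix Market + TSV sidecars
#'
#' Inverse of [read_counts()]: writes `counts.mtx`, `genes.tsv` and
#' `cells.tsv` under `dir`. Reading the files back reproduces the input
#' entry-for-entry.
#'
#' @param data a `SingleCellExperiment` with a `counts` assay.
#' @param dir output directory, created if needed.
#' @return invisibly, the three file paths.
#' @export
write_counts <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("counts.mtx", "genes.tsv", "cells.tsv"))
  writeMM(as(assay(data, "counts"), "CsparseMatrix"), paths[[1L]])
  write.table(data.frame(gene_id = rownames(data)),
              paths[[2L]], sep = "\t", quote = FALSE, row.names = FALSE)
  cd <- as.data.frame(colData(data))
  keep <- intersect(c("cell_id", "cell_type", "region", "donor", "condition"),
                    names(cd))
  write.table(cd[, keep, drop = FALSE],
              paths[[3L]], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Library-size normalized log2 expression
#'
#' Computes size factors as each cell's library size divided by the mean
#' library size, and a `logcounts` assay
#' `log2(count / size_factor + 1)`. The transform is monotone within each
#' cell, so per-cell expression ranks downstream do not depend on the size
#' factors; only cross-cell means do.
#'
#' @param data a `SingleCellExperiment` with a `counts` assay.
#' @return `data` with a `logcounts` assay and a `size_factor` column in
#'   `colData`.
#' @export
normalize_logcounts <- function(data) {
  counts <- assay(data, "counts")
  libsize <- colSums(counts)
  if (any(libsize <= 0)) {
    bad <- colnames(data)[libsize <= 0]
    treg_error("cells with zero library size: %s",
               paste(bad, collapse = ", "))
  }
  sf <- libsize / mean(libsize)
  lc <- as(counts %*% Diagonal(x = 1 / sf), "CsparseMatrix")
  lc@x <- log2(lc@x + 1)
  dimnames(lc) <- dimnames(counts)
  assay(data, "logcounts") <- lc
  colData(data)$size_factor <- sf
  data
}

#' Run configuration for the TREG workflow
#'
#' Collects the tunable parameters of the filtering and candidate steps.
#' Defaults mirror the reference analysis: keep the top half of expressed
#' genes, drop genes whose maximum proportion zero reaches 0.75, and
#' collapse cell types with at most 100 cells across regions into a single
#' region-ignorant group.
#'
#' @param top_expr_fraction fraction of genes kept by the expression
#'   filter, in (0, 1].
#' @param pz_cutoff strict upper bound on the maximum proportion zero, in
#'   (0, 1). Sparser datasets may warrant a higher value such as 0.85.
#' @param rare_group_min_cells cell types with at most this many cells in
#'   total are collapsed across regions.
#' @param seed optional integer seed recorded for reproducibility.
#' @param cell_type_order optional character vector giving the cell-type
#'   coding order for trend fits.
#' @return a list of class `treg_config`.
#' @export
run_config <- function(top_expr_fraction = 0.5, pz_cutoff = 0.75,
                       rare_group_min_cells = 100, seed = NULL,
                       cell_type_order = NULL) {
  if (!is.numeric(top_expr_fraction) || length(top_expr_fraction) != 1L ||
      top_expr_fraction <= 0 || top_expr_fraction > 1) {
    treg_error("top_expr_fraction must be a single value in (0, 1]")
  }
  if (!is.numeric(pz_cutoff) || length(pz_cutoff) != 1L ||
      pz_cutoff <= 0 || pz_cutoff >= 1) {
    treg_error("pz_cutoff must be a single value in (0, 1)")
  }
  if (!is.numeric(rare_group_min_cells) || length(rare_group_min_cells) != 1L ||
      rare_group_min_cells < 1 ||
      rare_group_min_cells != round(rare_group_min_cells)) {
    treg_error("rare_group_min_cells must be a positive integer")
  }
  if (!is.null(seed) &&
      (!is.numeric(seed) || length(seed) != 1L || seed != round(seed))) {
    treg_error("seed must be a single integer or NULL")
  }
  structure(list(top_expr_fraction = top_expr_fraction,
                 pz_cutoff = pz_cutoff,
                 rare_group_min_cells = as.integer(rare_group_min_cells),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 cell_type_order = cell_type_order),
            class = "treg_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected so typos fail loudly; missing keys fall back
#' to the [run_config()] defaults.
#'
#' @param path YAML file path.
#' @return a `treg_config` list.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) {
    treg_error("%s: unknown config keys: %s", path, paste(extra, collapse = ", "))
  }
  do.call(run_config, vals)
}

#' @export
print.treg_config <- function(x, ...) {
  cat("TREG run configuration\n")
  cat(sprintf("  top_expr_fraction:    %g\n", x$top_expr_fraction))
  cat(sprintf("  pz_cutoff:            %g\n", x$pz_cutoff))
  cat(sprintf("  rare_group_min_cells: %d\n", x$rare_group_min_cells))
  cat(sprintf("  seed:                 %s\n",
              if (is.null(x$seed)) "unset" else x$seed))
  cat(sprintf("  cell_type_order:      %s\n",
              if (is.null(x$cell_type_order)) "unset"
              else paste(x$cell_type_order, collapse = " > ")))
  invisible(x)
}
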