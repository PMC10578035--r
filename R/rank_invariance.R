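#' Per-cell expression ranks
#'
#' Ranks the genes within every cell independently, ascending, with ties
#' given the average rank: the most expressed gene in a cell receives rank
#' N, and tied values share the mean of the positions they span. Because
#' ranking is a per-cell operation, any per-cell monotone transform of the
#' counts (including library-size normalization) leaves the result
#' unchanged.
#'
#' @param expr genes x cells matrix of expression (logcounts), or a
#'   `SingleCellExperiment` whose `logcounts` assay is used.
#' @return genes x cells matrix of ranks, same dimnames as the input.
#' @export
rank_within_cells <- function(expr) {
  if (is(expr, "SummarizedExperiment")) {
    if (!"logcounts" %in% assayNames(expr)) expr <- normalize_logcounts(expr)
    expr <- assay(expr, "logcounts")
  }
  expr <- as.matrix(expr)
  if (nrow(expr) < 2L) treg_error("need at least 2 genes to rank")
  ranks <- apply(expr, 2L, avg_rank)
  dimnames(ranks) <- dimnames(expr)
  ranks
}

#' Rank genes by mean rank deviation within one cell type
#'
#' The per-cell-type step of the rank-invariance score. Within the given
#' cells: (a) the mean expression of every gene (on logcounts) is ranked
#' with average ties; (b) each cell's rank vector is compared to that
#' mean-expression rank by absolute difference; (c) the differences are
#' averaged per gene; (d) the per-gene means are ranked ascending with
#' average ties, so a gene whose rank barely moves across the cell type's
#' cells gets a low value.
#'
#' @param expr genes x cells logcounts matrix (all cells).
#' @param cell_ranks matrix from [rank_within_cells()] on the same cells.
#' @param cells index or logical vector selecting the cell type's cells.
#' @return numeric vector of length `nrow(expr)`: the step-(d) ranks.
#' @export
celltype_rank_of_deviation <- function(expr, cell_ranks, cells) {
  expr <- as.matrix(expr)
  sub_expr <- expr[, cells, drop = FALSE]
  sub_ranks <- cell_ranks[, cells, drop = FALSE]
  if (ncol(sub_expr) == 0L) treg_error("cell type has no cells")
  mean_expr_rank <- avg_rank(rowMeans(sub_expr))
  mean_abs_dev <- rowMeans(abs(sub_ranks - mean_expr_rank))
  out <- avg_rank(mean_abs_dev)
  names(out) <- rownames(expr)
  out
}

#' Rank invariance of every gene across cell types
#'
#' Scores each gene by how stable its within-cell expression rank is
#' across cells and across cell types. Per cell type, genes are ranked by
#' their mean absolute deviation from the cell type's mean-expression rank
#' ([celltype_rank_of_deviation()]); those ranks are summed over cell
#' types, and the sums are reverse-ranked (average ties) so the gene with
#' the smallest sum — the most rank-stable gene — receives the largest
#' value N. Region metadata is deliberately ignored here: cells are
#' grouped by cell type only.
#'
#' @param expr genes x cells logcounts matrix, or a
#'   `SingleCellExperiment` (its `logcounts` assay and `cell_type` column
#'   are used).
#' @param cell_types per-cell labels; taken from the object when `expr` is
#'   a `SingleCellExperiment`.
#' @return a `rank_invariance_result` with fields `gene_ids`,
#'   `per_celltype_rank` (cell types x genes), `rank_sum` and
#'   `rank_invariance` (higher = more invariant).
#' @export
rank_invariance <- function(expr, cell_types = NULL) {
  et <- .expr_and_types(expr, cell_types)
  mat <- et$mat
  cell_types <- et$cell_types
  if (is.null(cell_types)) treg_error("cell_types labels are required")
  cell_types <- as.character(cell_types)
  if (length(cell_types) != ncol(mat)) {
    treg_error("cell_types length (%d) does not match cells (%d)",
               length(cell_types), ncol(mat))
  }
  if (anyNA(cell_types) || any(!nzchar(cell_types))) {
    treg_error("missing or empty cell type label")
  }
  if (nrow(mat) < 2L) treg_error("need at least 2 genes")
  if (is.null(rownames(mat))) {
    rownames(mat) <- sprintf("gene%d", seq_len(nrow(mat)))
  }
  types <- sort(unique(cell_types))
  if (length(types) < 2L) {
    treg_log("WARN", "only %d cell type present; rank invariance degenerates to within-type stability",
             length(types))
  }
  cell_ranks <- rank_within_cells(mat)
  per_ct <- t(vapply(types, function(tp) {
    celltype_rank_of_deviation(mat, cell_ranks, which(cell_types == tp))
  }, numeric(nrow(mat))))
  rownames(per_ct) <- types
  rank_sum <- colSums(per_ct)
  ri <- avg_rank(-rank_sum)
  names(ri) <- rownames(mat)
  structure(list(gene_ids = rownames(mat),
                 per_celltype_rank = per_ct,
                 rank_sum = rank_sum,
                 rank_invariance = ri),
            class = "rank_invariance_result")
}

#' @export
print.rank_invariance_result <- function(x, ...) {
  n <- length(x$gene_ids)
  cat(sprintf("Rank invariance over %d genes, %d cell types\n",
              n, nrow(x$per_celltype_rank)))
  top <- head(x$gene_ids[order_desc_stable(x$rank_invariance)], 5L)
  cat("  top genes:", paste(top, collapse = ", "), "\n")
  invisible(x)
}

#' Candidate genes with the highest rank invariance
#'
#' @param result a `rank_invariance_result`.
#' @param n number of candidates, at most the number of genes.
#' @return character vector of gene ids, sorted by decreasing rank
#'   invariance; ties broken by input gene order (stable).
#' @export
top_candidates <- function(result, n = 50) {
  stopifnot(is(result, "rank_invariance_result"))
  N <- length(result$gene_ids)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    treg_error("n must be a positive integer")
  }
  if (n > N) treg_error("n (%d) exceeds number of genes (%d)", n, N)
  result$gene_ids[order_desc_stable(result$rank_invariance)][seq_len(n)]
}

#' Serialize a rank-invariance result to TSV
#'
#' Columns: `gene_id`, one step-(d) rank column per cell type, `rank_sum`,
#' `rank_invariance`.
#'
#' @param result a `rank_invariance_result`.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_rank_invariance <- function(result, path) {
  df <- data.frame(gene_id = result$gene_ids,
                   t(result$per_celltype_rank),
                   rank_sum = result$rank_sum,
                   rank_invariance = result$rank_invariance,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
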