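#' Total RNA expression per cell
#'
#' A nucleus's total RNA content is estimated by the log2 of its total UMI
#' count (the column sum of the raw count matrix).
#'
#' @param data a `SingleCellExperiment` with a `counts` assay.
#' @return named numeric vector, log2 library size per cell.
#' @export
total_expression <- function(data) {
  libsize <- colSums(assay(data, "counts"))
  if (any(libsize <= 0)) {
    treg_error("cells with zero library size: %s",
               paste(colnames(data)[libsize <= 0], collapse = ", "))
  }
  out <- log2(libsize)
  names(out) <- colnames(data)
  out
}

#' Per-gene linear models of expression against total RNA
#'
#' Fits, for every requested gene, the ordinary least squares model
#' `log2(count + 1) ~ log2(sum) + cellType` across all cells, where
#' `log2(sum)` is the cell's log2 total UMI count and cell type enters as
#' indicator contrasts against the first level in sorted label order. The
#' coefficient on `log2(sum)` (`beta_total`), its standard error and
#' t-statistic are reported; genes are ranked by t-statistic, descending.
#' A gene whose expression tracks total RNA content earns a large positive
#' t-statistic, corroborating rank-invariance candidates.
#'
#' With a single cell type the cell-type term is dropped automatically.
#' A perfect fit leaves the t-statistic undefined: such genes get `NaN`
#' and are ranked last, with a warning.
#'
#' @param data a `SingleCellExperiment` with a `counts` assay.
#' @param genes optional character vector of gene ids to fit (default all).
#' @return data.frame with columns `gene_id`, `beta_total`, `se`,
#'   `t_stat`, `t_rank`, `n_obs`.
#' @export
fit_gene_total_models <- function(data, genes = NULL) {
  counts <- assay(data, "counts")
  if (is.null(genes)) genes <- rownames(data)
  missing <- setdiff(genes, rownames(data))
  if (length(missing)) {
    treg_error("unknown genes: %s", paste(missing, collapse = ", "))
  }
  log_sum <- total_expression(data)
  ct <- as.character(colData(data)$cell_type)
  n <- ncol(counts)
  levels <- sort(unique(ct))
  if (any(table(ct) == 1L)) {
    treg_log("WARN", "cell types with a single cell: %s",
             paste(names(which(table(ct) == 1L)), collapse = ", "))
  }
  X <- cbind(`(Intercept)` = 1, log2_sum = log_sum)
  if (length(levels) >= 2L) {
    for (lv in levels[-1L]) {
      X <- cbind(X, as.numeric(ct == lv))
      colnames(X)[ncol(X)] <- paste0("cell_type", lv)
    }
  }
  p <- ncol(X)
  if (n <= p) treg_error("need more cells (%d) than coefficients (%d)", n, p)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, p)]]
    treg_error("rank-deficient design; collinear columns: %s",
               paste(bad, collapse = ", "))
  }
  Y <- t(as.matrix(log2(counts[genes, , drop = FALSE] + 1)))
  beta <- qr.coef(qrX, Y)
  res <- Y - X %*% beta
  rss <- colSums(res^2)
  sigma2 <- rss / (n - p)
  xtx_inv_22 <- chol2inv(qr.R(qrX))[2L, 2L]
  se <- sqrt(sigma2 * xtx_inv_22)
  t_stat <- beta["log2_sum", ] / se
  perfect <- sigma2 < .Machine$double.eps * n
  if (any(perfect)) {
    t_stat[perfect] <- NaN
    warning(sprintf("zero residual variance for %s; t undefined, ranked last",
                    paste(genes[perfect], collapse = ", ")))
  }
  ord <- order(-xtfrm(ifelse(is.finite(t_stat), t_stat, -Inf)),
               seq_along(t_stat))
  t_rank <- integer(length(genes))
  t_rank[ord] <- seq_along(genes)
  data.frame(gene_id = genes,
             beta_total = unname(beta["log2_sum", ]),
             se = unname(se),
             t_stat = unname(t_stat),
             t_rank = t_rank,
             n_obs = n,
             stringsAsFactors = FALSE)
}
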