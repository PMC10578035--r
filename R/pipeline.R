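#' End-to-end candidate TREG identification
#'
#' Convenience wrapper running the full workflow on one dataset:
#' normalization, expression filter, proportion-zero filter, rank
#' invariance, and top-n candidate selection.
#'
#' @param data a `SingleCellExperiment` with a `counts` assay and
#'   `cell_type` metadata.
#' @param config a [run_config()].
#' @param top_n number of candidates to return (capped at the number of
#'   genes surviving the filters).
#' @return list with `candidates` (character vector), `rank_invariance`
#'   (a `rank_invariance_result`) and `filters` (the [run_gene_filters()]
#'   output).
#' @export
treg_candidates <- function(data, config = run_config(), top_n = 50) {
  filters <- run_gene_filters(data, config)
  if (nrow(filters$data) < 2L) {
    treg_error("fewer than 2 genes survived filtering; relax the cutoffs")
  }
  ri <- rank_invariance(filters$data)
  n <- min(top_n, length(ri$gene_ids))
  list(candidates = top_candidates(ri, n),
       rank_invariance = ri,
       filters = filters)
}
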