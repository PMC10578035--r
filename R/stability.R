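#' Overlap report for candidate gene sets
#'
#' Quantifies agreement between candidate lists obtained under different
#' conditions (full data vs case-only vs control-only, or per region):
#' the genes shared by all sets, the union, the shared percentage
#' (100 * shared / union, one decimal), and the pairwise intersection
#' counts.
#'
#' @param sets named list of character vectors (candidate gene sets);
#'   at least two, non-empty, uniquely named.
#' @return an `overlap_report`: `shared_all` (count), `shared_genes`,
#'   `union` (count), `pct_shared`, `pairwise` (matrix).
#' @export
#' @examples
#' overlap_report(list(a = c("A", "B", "C"), b = c("B", "C", "D"), c = c("B", "C")))
overlap_report <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L) {
    treg_error("need at least 2 candidate sets")
  }
  if (is.null(names(sets)) || anyDuplicated(names(sets)) ||
      any(!nzchar(names(sets)))) {
    treg_error("sets must be uniquely named")
  }
  if (any(lengths(sets) == 0L)) treg_error("empty candidate set")
  sets <- lapply(sets, unique)
  shared <- Reduce(intersect, sets)
  un <- Reduce(union, sets)
  k <- length(sets)
  pairwise <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      pairwise[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  structure(list(shared_all = length(shared),
                 shared_genes = sort(shared),
                 union = length(un),
                 pct_shared = round(100 * length(shared) / length(un), 1L),
                 pairwise = pairwise),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("%d genes shared by all sets (%.1f%% of %d unique genes)\n",
              x$shared_all, x$pct_shared, x$union))
  cat("pairwise intersections:\n")
  print(x$pairwise)
  invisible(x)
}

#' Serialize an overlap report to TSV plus a count table
#'
#' Writes a two-column summary TSV and appends a plain-text pairwise
#' intersection table.
#'
#' @param report an `overlap_report`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_overlap_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("metric\tvalue",
               sprintf("shared_all\t%d", report$shared_all),
               sprintf("union\t%d", report$union),
               sprintf("pct_shared\t%.1f", report$pct_shared),
               sprintf("shared_genes\t%s",
                       paste(report$shared_genes, collapse = ",")),
               "", "pairwise intersection counts:"), con)
  utils::write.table(report$pairwise, con, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Candidate TREGs from the full data and from each partition
#'
#' Runs the whole candidate workflow (expression filter, proportion-zero
#' filter, rank invariance, top-n selection) on the full dataset and
#' separately on every level of a metadata column (e.g. `condition` for a
#' case/control split, or `region`), returning the candidate lists as
#' named sets ready for [overlap_report()]. The full-data set is named
#' `"all"`.
#'
#' @param data a `SingleCellExperiment`.
#' @param partition_by name of a `colData` column.
#' @param config a [run_config()]; a sparser partition may warrant a
#'   higher `pz_cutoff` (e.g. 0.85).
#' @param top_n candidates per run (default 50).
#' @return named list of character vectors (class `candidate_sets`).
#' @export
multi_run_candidates <- function(data, partition_by, config = run_config(),
                                 top_n = 50) {
  cd <- colData(data)
  if (!partition_by %in% names(cd)) {
    treg_error("partition column '%s' not present in cell metadata",
               partition_by)
  }
  part <- as.character(cd[[partition_by]])
  levels <- sort(unique(part))
  runs <- c(list(all = seq_len(ncol(data))),
            stats::setNames(lapply(levels, function(lv) which(part == lv)),
                            levels))
  sets <- lapply(names(runs), function(nm) {
    treg_log("INFO", "candidate run '%s' (%d cells)", nm, length(runs[[nm]]))
    filtered <- run_gene_filters(data[, runs[[nm]]], config)
    ri <- rank_invariance(filtered$data)
    top_candidates(ri, min(top_n, length(ri$gene_ids)))
  })
  names(sets) <- names(runs)
  structure(sets, class = "candidate_sets")
}

#' Read / write gene sets as one-gene-per-line text files
#'
#' @param path file path.
#' @return `read_gene_set`: character vector of gene ids.
#' @export
read_gene_set <- function(path) {
  genes <- readLines(path)
  genes[nzchar(genes)]
}

#' @rdname read_gene_set
#' @param genes character vector of gene ids.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}
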