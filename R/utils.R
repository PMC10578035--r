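#' Log a message to stderr with a level prefix
#'
#' Prefixes are `INFO`, `WARN` or `ERROR`; output goes to the message
#' stream so it never pollutes TSV written to stdout.
#'
#' @param level character, one of "INFO", "WARN", "ERROR".
#' @param fmt sprintf-style format string.
#' @param ... values interpolated into `fmt`.
#' @return invisibly, the formatted line.
#' @keywords internal
treg_log <- function(level = "INFO", fmt = "", ...) {
  line <- sprintf("[%s] %s", level, sprintf(fmt, ...))
  message(line)
  invisible(line)
}

# stop() with a consistent error class so callers (and the CLI) can
# distinguish data errors from programming errors
treg_error <- function(fmt, ..., class = "treg_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

# average-tie ranks, ascending (ties share the mean of their positions);
# thin wrapper so the tie policy is stated once
avg_rank <- function(x) rank(x, ties.method = "average")

# stable descending order: ties resolved by original position
order_desc_stable <- function(x) order(-xtfrm(x), seq_along(x))

# extract the logcounts matrix and cell-type labels from either a
# SingleCellExperiment or a plain matrix + labels pair
.expr_and_types <- function(expr, cell_types = NULL) {
  if (is(expr, "SummarizedExperiment")) {
    if (!"logcounts" %in% assayNames(expr)) {
      expr <- normalize_logcounts(expr)
    }
    if (is.null(cell_types)) {
      cell_types <- as.character(colData(expr)$cell_type)
    }
    mat <- as.matrix(assay(expr, "logcounts"))
  } else {
    mat <- as.matrix(expr)
  }
  list(mat = mat, cell_types = cell_types)
}
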