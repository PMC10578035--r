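#' Default column map for per-nucleus segmentation CSVs
#'
#' Segmentation software exports one row per nucleus with
#' software-specific column names; the column map is the supported
#' contract between those exports and this package. `markers` maps marker
#' gene names to the CSV columns holding their per-nucleus signal counts.
#'
#' @param nucleus_id,section_id,x,y,nuclear_area,target_puncta CSV column
#'   names for the respective fields.
#' @param markers named character vector: marker gene -> CSV column.
#' @return a list usable as `column_map` in [load_nucleus_table()].
#' @export
nucleus_column_map <- function(nucleus_id = "nucleus_id",
                               section_id = "section_id",
                               x = "x", y = "y",
                               nuclear_area = "nuclear_area",
                               target_puncta = "target_puncta",
                               markers = c(SLC17A7 = "SLC17A7",
                                           GAD1 = "GAD1",
                                           MBP = "MBP")) {
  list(nucleus_id = nucleus_id, section_id = section_id, x = x, y = y,
       nuclear_area = nuclear_area, target_puncta = target_puncta,
       markers = markers)
}

#' Load a per-nucleus segmentation table from CSV
#'
#' Reads a per-object CSV export (one row per segmented nucleus) into a
#' typed `nucleus_table`: standardized columns `nucleus_id`, `section_id`,
#' `x`, `y`, `nuclear_area`, one `marker_<gene>` count column per mapped
#' marker, `target_puncta`, plus bookkeeping columns `qc_excluded`
#' (initially FALSE) and `phenotype` (unassigned until
#' [phenotype_nuclei()]). Unmapped columns are ignored; rows with missing
#' required fields are dropped with their row numbers logged. A marker
#' column named in the map but absent from the CSV restricts the
#' assignable phenotypes and is logged rather than fatal.
#'
#' @param csv_path path to the CSV.
#' @param column_map a [nucleus_column_map()].
#' @return a data.frame of class `nucleus_table`; the mapped marker genes
#'   are recorded in the `markers` attribute.
#' @export
load_nucleus_table <- function(csv_path, column_map = nucleus_column_map()) {
  raw <- read.csv(csv_path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("nucleus_id", "section_id", "x", "y", "nuclear_area",
                "target_puncta")
  for (field in required) {
    if (!column_map[[field]] %in% names(raw)) {
      treg_error("%s: missing required column '%s' (mapped field %s)",
                 csv_path, column_map[[field]], field)
    }
  }
  present <- column_map$markers[column_map$markers %in% names(raw)]
  absent <- setdiff(names(column_map$markers), names(present))
  if (length(absent)) {
    treg_log("WARN", "marker column(s) absent from %s: %s; phenotypes restricted",
             csv_path, paste(absent, collapse = ", "))
  }
  tab <- data.frame(
    nucleus_id = as.character(raw[[column_map$nucleus_id]]),
    section_id = as.character(raw[[column_map$section_id]]),
    x = as.numeric(raw[[column_map$x]]),
    y = as.numeric(raw[[column_map$y]]),
    nuclear_area = as.numeric(raw[[column_map$nuclear_area]]),
    target_puncta = as.numeric(raw[[column_map$target_puncta]]),
    stringsAsFactors = FALSE
  )
  for (g in names(present)) {
    tab[[paste0("marker_", g)]] <- as.numeric(raw[[present[[g]]]])
  }
  incomplete <- !stats::complete.cases(tab) | tab$nuclear_area <= 0 |
    tab$target_puncta < 0
  if (any(incomplete)) {
    treg_log("WARN", "dropping %d row(s) with missing/invalid required fields: rows %s",
             sum(incomplete), paste(which(incomplete), collapse = ", "))
    tab <- tab[!incomplete, , drop = FALSE]
  }
  tab$qc_excluded <- FALSE
  tab$phenotype <- NA_character_
  rownames(tab) <- NULL
  structure(tab, markers = names(present), class = c("nucleus_table", "data.frame"))
}

#' Write a nucleus table to CSV
#'
#' Writes the standardized columns so that [load_nucleus_table()] with the
#' default column map (markers mapped to their `marker_<gene>` columns)
#' round-trips the table.
#'
#' @param table a `nucleus_table`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_nucleus_table <- function(table, path) {
  out <- as.data.frame(table)
  out$qc_excluded <- NULL
  out$phenotype <- NULL
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Mark nuclei as excluded by quality control
#'
#' Segmentation artifacts (tissue tears, bubbles, out-of-focus fields) are
#' identified by inspection and supplied here either as rectangles in
#' image coordinates or as explicit nucleus ids; matching nuclei get
#' `qc_excluded = TRUE` and are ignored by every summary.
#'
#' @param table a `nucleus_table`.
#' @param exclude_rect optional data.frame with columns `xmin`, `xmax`,
#'   `ymin`, `ymax`, one exclusion rectangle per row (closed bounds).
#' @param exclude_ids optional character vector of nucleus ids.
#' @return the table with `qc_excluded` updated.
#' @export
apply_qc <- function(table, exclude_rect = NULL, exclude_ids = NULL) {
  stopifnot(is(table, "nucleus_table"))
  excl <- table$qc_excluded
  if (!is.null(exclude_rect) && nrow(exclude_rect)) {
    for (r in seq_len(nrow(exclude_rect))) {
      rc <- exclude_rect[r, ]
      excl <- excl | (table$x >= rc$xmin & table$x <= rc$xmax &
                        table$y >= rc$ymin & table$y <= rc$ymax)
    }
  }
  if (!is.null(exclude_ids)) {
    excl <- excl | table$nucleus_id %in% exclude_ids
  }
  treg_log("INFO", "QC: excluding %d of %d nuclei", sum(excl), nrow(table))
  table$qc_excluded <- excl
  table
}

#' Assign cell-type phenotypes from marker signals
#'
#' A nucleus expressing exactly one marker at or above `threshold` copies
#' is assigned that marker's phenotype; two or more positive markers give
#' `"Multi"` (ambiguous); none gives `"Other"` (unlabeled cell types).
#' Phenotypes whose marker column is missing from the table are dropped
#' from the assignable set with a log line — e.g. when a marker had to be
#' omitted from a probe combination, that phenotype cannot be called.
#'
#' @param table a `nucleus_table`.
#' @param markers named character vector phenotype -> marker gene.
#' @param threshold minimum signal count to call a marker positive
#'   (default 1 detected copy; changing it changes the phenotype
#'   composition, so it is logged prominently).
#' @return the table with `phenotype` filled for every nucleus.
#' @export
phenotype_nuclei <- function(table,
                             markers = c(Excit = "SLC17A7", Inhib = "GAD1",
                                         Oligo = "MBP"),
                             threshold = 1) {
  stopifnot(is(table, "nucleus_table"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 1) {
    treg_error("threshold must be a positive count")
  }
  cols <- paste0("marker_", markers)
  usable <- cols %in% names(table)
  if (any(!usable)) {
    treg_log("WARN", "markers without columns: %s; phenotypes %s cannot be assigned",
             paste(markers[!usable], collapse = ", "),
             paste(names(markers)[!usable], collapse = ", "))
  }
  markers <- markers[usable]
  cols <- cols[usable]
  if (!length(markers)) treg_error("no usable marker columns")
  treg_log("INFO", "phenotyping with threshold >= %g on markers: %s",
           threshold, paste(sprintf("%s=%s", names(markers), markers),
                            collapse = ", "))
  pos <- vapply(cols, function(cl) table[[cl]] >= threshold,
                logical(nrow(table)))
  pos <- matrix(pos, nrow = nrow(table))
  n_pos <- rowSums(pos)
  pheno <- rep("Other", nrow(table))
  pheno[n_pos >= 2L] <- "Multi"
  single <- which(n_pos == 1L)
  if (length(single)) {
    pheno[single] <- names(markers)[apply(pos[single, , drop = FALSE], 1L,
                                          which.max)]
  }
  table$phenotype <- pheno
  table
}

#' Per-gene summary of a nucleus table
#'
#' Over all non-excluded nuclei: the proportion with any target puncta,
#' the mean puncta count, and the standardized trend of puncta over the
#' ordered cell-type phenotypes. Only nuclei whose phenotype appears in
#' `cell_type_order` enter the trend fit (`Multi` and `Other` are
#' excluded from it, not from the proportions).
#'
#' @param table a phenotyped `nucleus_table`.
#' @param gene name of the probed gene (annotation only).
#' @param cell_type_order phenotype coding order for the trend,
#'   conventionally decreasing total RNA.
#' @return a `gene_summary` list: `gene`, `prop_nonzero`, `mean_puncta`,
#'   `trend` (a [trend_fit()]), `n_nuclei`.
#' @export
summarize_gene <- function(table, gene,
                           cell_type_order = c("Excit", "Inhib", "Oligo")) {
  stopifnot(is(table, "nucleus_table"))
  keep <- !table$qc_excluded
  if (!any(keep)) treg_error("no non-excluded nuclei to summarize")
  tab <- table[keep, , drop = FALSE]
  prop_nonzero <- mean(tab$target_puncta > 0)
  mean_puncta <- mean(tab$target_puncta)
  trend_rows <- tab$phenotype %in% cell_type_order
  trend <- standardized_slope(tab$target_puncta[trend_rows],
                              tab$phenotype[trend_rows],
                              cell_type_order)
  structure(list(gene = gene, prop_nonzero = prop_nonzero,
                 mean_puncta = mean_puncta, trend = trend,
                 n_nuclei = nrow(tab)),
            class = "gene_summary")
}

#' @export
print.gene_summary <- function(x, ...) {
  cat(sprintf("%s: %d nuclei, prop non-zero %.2f, mean puncta %.2f\n",
              x$gene, x$n_nuclei, x$prop_nonzero, x$mean_puncta))
  cat(sprintf("  std beta %.2f (95%% CI %.2f, %.2f)\n",
              x$trend$std_beta, x$trend$ci_std_low, x$trend$ci_std_high))
  invisible(x)
}
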