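#' Specification for a synthetic annotated count matrix
#'
#' Describes a simulated sc/snRNA-seq dataset with known ground truth,
#' emulating the structure the TREG workflow exercises: cell types with
#' distinct library-size distributions (neurons carry more RNA than
#' glia), planted rank-invariant genes holding a constant, distinct share
#' of every cell type's transcriptome (constant relative expression
#' implies a constant within-cell rank), cell-type marker genes elevated
#' only in their own type, background noise genes with small
#' Dirichlet-perturbed shares, and extra dropout on the noise genes.
#'
#' Default library-size distributions follow cortical snRNA-seq
#' experience: excitatory neurons around 20k UMIs per nucleus,
#' inhibitory neurons around 13k, oligodendrocytes around 5k, each
#' log-normal with sdlog 0.4.
#'
#' @param cell_types list of `list(name, n_cells, libsize_log_mean,
#'   libsize_log_sd)`, ordered by decreasing expected library size.
#' @param n_treg number of planted rank-invariant genes.
#' @param n_marker marker genes per cell type.
#' @param n_noise background noise genes.
#' @param dropout_extra additional per-entry zeroing probability applied
#'   to noise genes, in \[0, 1).
#' @param n_conditions number of simulated conditions; under more than
#'   one, each condition re-draws its noise shares and jitters its marker
#'   shares while the planted genes stay identical, emulating
#'   condition-specific structure around shared TREGs.
#' @param seed integer seed; all draws are reproducible from it.
#' @return a list of class `sim_spec`.
#' @export
sim_spec <- function(cell_types = list(
                       list(name = "Excit", n_cells = 300,
                            libsize_log_mean = log(20000), libsize_log_sd = 0.4),
                       list(name = "Inhib", n_cells = 300,
                            libsize_log_mean = log(13000), libsize_log_sd = 0.4),
                       list(name = "Oligo", n_cells = 300,
                            libsize_log_mean = log(5000), libsize_log_sd = 0.4)),
                     n_treg = 5, n_marker = 5, n_noise = 80,
                     dropout_extra = 0.2, n_conditions = 1, seed = 1) {
  if (length(cell_types) < 2L) treg_error("need at least 2 cell types")
  for (ct in cell_types) {
    if (!all(c("name", "n_cells", "libsize_log_mean", "libsize_log_sd") %in%
             names(ct))) {
      treg_error("each cell type needs name, n_cells, libsize_log_mean, libsize_log_sd")
    }
    if (ct$n_cells < 1) treg_error("n_cells must be positive")
    if (ct$libsize_log_sd <= 0) treg_error("libsize_log_sd must be positive")
  }
  exp_lib <- vapply(cell_types,
                    function(ct) exp(ct$libsize_log_mean + ct$libsize_log_sd^2 / 2),
                    0)
  if (is.unsorted(rev(exp_lib))) {
    treg_error("cell_types must be ordered by decreasing expected library size")
  }
  if (n_treg < 1 || n_marker < 0 || n_noise < 0 ||
      n_treg + n_marker + n_noise < 2) {
    treg_error("invalid gene counts")
  }
  if (dropout_extra < 0 || dropout_extra >= 1) {
    treg_error("dropout_extra must be in [0, 1)")
  }
  if (n_conditions < 1) treg_error("n_conditions must be positive")
  structure(list(cell_types = cell_types, n_treg = as.integer(n_treg),
                 n_marker = as.integer(n_marker), n_noise = as.integer(n_noise),
                 dropout_extra = dropout_extra,
                 n_conditions = as.integer(n_conditions),
                 seed = as.integer(seed)),
            class = "sim_spec")
}

# per-condition gene-share matrix (genes x cell types); planted TREG
# weights are deterministic so they are identical across conditions
.sim_weights <- function(spec, truth, types) {
  G <- length(truth)
  K <- length(types)
  w <- matrix(0, G, K, dimnames = list(names(truth), types))
  treg_rows <- which(truth == "treg")
  if (length(treg_rows)) {
    w[treg_rows, ] <- seq(2, 4, length.out = length(treg_rows))
  }
  for (k in seq_len(K)) {
    own <- which(truth == paste0("marker:", types[[k]]))
    others <- which(startsWith(truth, "marker:") &
                      truth != paste0("marker:", types[[k]]))
    w[own, k] <- 6 * runif(length(own), 0.8, 1.2)
    w[others, k] <- 0.05 * runif(length(others), 0.5, 1.5)
  }
  noise_rows <- which(truth == "noise")
  if (length(noise_rows)) {
    base <- rgamma(length(noise_rows), shape = 2, rate = 4)
    for (k in seq_len(K)) {
      w[noise_rows, k] <- base * rgamma(length(noise_rows), 10, 10)
    }
  }
  sweep(w, 2L, colSums(w), "/")
}

#' Simulate an annotated count matrix with planted structure
#'
#' Draws each cell's library size log-normally from its cell type's
#' distribution, then draws gene counts multinomially from the cell
#' type's gene-share vector, and finally zeroes noise-gene entries with
#' probability `dropout_extra`. Because counts are multinomial
#' conditioned on the library size, a gene's expected within-cell rank is
#' governed entirely by its share, which is what makes constant-share
#' TREGs plantable exactly. Random-number use is split per component
#' (library sizes, gene shares, counts, dropout) so changing the gene
#' roster does not perturb the cell library sizes.
#'
#' @param spec a [sim_spec()].
#' @return a `SingleCellExperiment`; `rowData(x)$truth` labels each gene
#'   `"treg"`, `"marker:<type>"` or `"noise"`, and `colData` carries
#'   `cell_type` and `condition`.
#' @export
simulate_counts <- function(spec) {
  stopifnot(is(spec, "sim_spec"))
  types <- vapply(spec$cell_types, `[[`, "", "name")
  truth <- c(rep("treg", spec$n_treg),
             unlist(lapply(types, function(tp)
               rep(paste0("marker:", tp), spec$n_marker))),
             rep("noise", spec$n_noise))
  gene_ids <- c(sprintf("TREG%02d", seq_len(spec$n_treg)),
                unlist(lapply(types, function(tp)
                  sprintf("%s_M%02d", toupper(tp), seq_len(spec$n_marker)))),
                sprintf("NOISE%03d", seq_len(spec$n_noise)))
  names(truth) <- gene_ids
  G <- length(gene_ids)
  n_per_cond <- sum(vapply(spec$cell_types, `[[`, 0, "n_cells"))

  # component 1: library sizes (independent of the gene roster)
  set.seed(spec$seed)
  lib <- unlist(lapply(seq_len(spec$n_conditions), function(cond) {
    unlist(lapply(spec$cell_types, function(ct) {
      pmax(1, round(rlnorm(ct$n_cells, ct$libsize_log_mean, ct$libsize_log_sd)))
    }))
  }))
  cell_type <- rep(unlist(lapply(spec$cell_types, function(ct)
    rep(ct$name, ct$n_cells))), spec$n_conditions)
  condition <- rep(sprintf("cond%d", seq_len(spec$n_conditions)),
                   each = n_per_cond)

  # component 2: gene shares per condition
  set.seed(spec$seed + 1L)
  shares <- lapply(seq_len(spec$n_conditions), function(cond)
    .sim_weights(spec, truth, types))

  # component 3: multinomial counts
  set.seed(spec$seed + 2L)
  counts <- matrix(0L, G, length(lib))
  for (z in seq_along(lib)) {
    p <- shares[[match(condition[[z]], unique(condition))]][, cell_type[[z]]]
    counts[, z] <- rmultinom(1L, size = lib[[z]], prob = p)
  }

  # component 4: extra dropout on noise genes
  set.seed(spec$seed + 3L)
  noise_rows <- which(truth == "noise")
  if (length(noise_rows) && spec$dropout_extra > 0) {
    keep <- matrix(rbinom(length(noise_rows) * length(lib), 1L,
                          1 - spec$dropout_extra),
                   length(noise_rows), length(lib))
    counts[noise_rows, ] <- counts[noise_rows, , drop = FALSE] * keep
  }

  cell_ids <- sprintf("cell%04d", seq_along(lib))
  out <- annotated_counts(counts,
                          data.frame(cell_type = cell_type,
                                     condition = condition,
                                     stringsAsFactors = FALSE),
                          gene_ids = gene_ids, cell_ids = cell_ids)
  rowData(out)$truth <- unname(truth)
  out
}

#' Simulate a per-nucleus segmentation table
#'
#' Generates one row per nucleus with a known phenotype: target puncta
#' Poisson with a phenotype-specific mean, nuclear area log-normal around
#' a phenotype-specific mean (neuronal nuclei larger than glial), marker
#' counts consistent with the assigned phenotype (own marker at least one
#' copy, other markers zero), and uniform image coordinates. Defaults
#' emulate a cortical section probed for a TREG whose expression tracks
#' total RNA: puncta means decrease linearly Excit > Inhib > Oligo (8, 5,
#' 2 puncta — a true slope of -3 per cell-type code), and areas decrease
#' 90, 70, 40 square micrometres.
#'
#' @param n_per_type named integer vector: nuclei per phenotype.
#' @param puncta_means named numeric vector: mean target puncta per
#'   phenotype.
#' @param area_means named numeric vector: mean nuclear area per
#'   phenotype (square micrometres).
#' @param seed integer seed.
#' @param section_id section label for all rows.
#' @param markers named character vector phenotype -> marker gene.
#' @return a `nucleus_table` (see [load_nucleus_table()]); phenotype is
#'   left unassigned so [phenotype_nuclei()] can be exercised, but the
#'   generating phenotype is recorded in the `true_phenotype` column.
#' @export
simulate_nucleus_table <- function(n_per_type = c(Excit = 100, Inhib = 100,
                                                  Oligo = 100),
                                   puncta_means = c(Excit = 8, Inhib = 5,
                                                    Oligo = 2),
                                   area_means = c(Excit = 90, Inhib = 70,
                                                  Oligo = 40),
                                   seed = 1, section_id = "S1",
                                   markers = c(Excit = "SLC17A7",
                                               Inhib = "GAD1",
                                               Oligo = "MBP")) {
  types <- names(n_per_type)
  if (is.null(types) ||
      !all(types %in% names(puncta_means)) ||
      !all(types %in% names(area_means)) ||
      !all(types %in% names(markers))) {
    treg_error("n_per_type, puncta_means, area_means and markers must share a common named cell-type set")
  }
  if (any(n_per_type < 1) || any(puncta_means < 0) || any(area_means <= 0)) {
    treg_error("invalid simulation parameters")
  }
  set.seed(seed)
  n <- sum(n_per_type)
  pheno <- rep(types, n_per_type)
  tab <- data.frame(
    nucleus_id = sprintf("N%05d", seq_len(n)),
    section_id = section_id,
    x = runif(n, 0, 1000),
    y = runif(n, 0, 1000),
    nuclear_area = rlnorm(n, log(area_means[pheno]) - 0.25^2 / 2, 0.25),
    target_puncta = rpois(n, puncta_means[pheno]),
    stringsAsFactors = FALSE
  )
  for (g in markers) tab[[paste0("marker_", g)]] <- 0
  for (tp in types) {
    rows <- pheno == tp
    tab[rows, paste0("marker_", markers[[tp]])] <- 1L + rpois(sum(rows), 4)
  }
  tab$true_phenotype <- pheno
  tab$qc_excluded <- FALSE
  tab$phenotype <- NA_character_
  structure(tab, markers = unname(markers),
            class = c("nucleus_table", "data.frame"))
}
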