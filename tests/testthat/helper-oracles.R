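# Independent oracles used across tests. These are deliberately naive
# (quadratic counting, explicit loops, closed-form normal equations) so
# they share no code path with the implementation they check.

# average-tie ascending ranks by brute-force pairwise counting
brute_rank <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[[i]]) + (sum(x == x[[i]]) + 1) / 2
  }, numeric(1))
}

# literal loop implementation of the eight rank-invariance steps:
# (ii) rank genes within every cell; per cell type (iii) rank the mean
# logcounts, (iv-v) mean absolute rank deviation per gene, (vi) rank the
# deviations; (vii) repeat per type; (viii) reverse-rank the summed ranks
ri_oracle <- function(logmat, types) {
  G <- nrow(logmat)
  n <- ncol(logmat)
  cell_ranks <- matrix(NA_real_, G, n)
  for (z in seq_len(n)) cell_ranks[, z] <- brute_rank(logmat[, z])
  type_levels <- sort(unique(types))
  per_ct <- matrix(NA_real_, length(type_levels), G)
  for (k in seq_along(type_levels)) {
    cells <- which(types == type_levels[[k]])
    mean_expr <- numeric(G)
    for (g in seq_len(G)) {
      s <- 0
      for (z in cells) s <- s + logmat[g, z]
      mean_expr[[g]] <- s / length(cells)
    }
    mean_rank <- brute_rank(mean_expr)
    mad_g <- numeric(G)
    for (g in seq_len(G)) {
      s <- 0
      for (z in cells) s <- s + abs(cell_ranks[g, z] - mean_rank[[g]])
      mad_g[[g]] <- s / length(cells)
    }
    per_ct[k, ] <- brute_rank(mad_g)
  }
  rank_sum <- numeric(G)
  for (g in seq_len(G)) rank_sum[[g]] <- sum(per_ct[, g])
  list(per_ct = per_ct, rank_sum = rank_sum,
       rank_invariance = brute_rank(-rank_sum))
}

# ordinary least squares by explicit normal equations
ols_oracle <- function(X, y) {
  XtX_inv <- solve(t(X) %*% X)
  beta <- XtX_inv %*% t(X) %*% y
  res <- y - X %*% beta
  n <- nrow(X)
  p <- ncol(X)
  sigma2 <- sum(res^2) / (n - p)
  list(beta = drop(beta), se = sqrt(sigma2 * diag(XtX_inv)))
}

# small random annotated counts object for fixtures
random_counts <- function(G, n, types = c("A", "B"), seed = 1,
                          lambda = 5) {
  set.seed(seed)
  m <- matrix(rpois(G * n, lambda), G, n)
  # guarantee positive library sizes
  zero_cells <- colSums(m) == 0
  m[1L, zero_cells] <- 1L
  annotated_counts(m,
                   data.frame(cell_type = rep_len(types, n),
                              stringsAsFactors = FALSE),
                   gene_ids = sprintf("g%03d", seq_len(G)),
                   cell_ids = sprintf("c%03d", seq_len(n)))
}

# suppress the package's INFO logging inside tests
quiet <- function(expr) suppressMessages(expr)
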