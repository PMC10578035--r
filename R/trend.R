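#' Construct a trend fit from summary statistics
#'
#' A trend fit describes the linear slope of an outcome (total UMIs, or
#' smFISH puncta per nucleus) over ordered cell-type codes, together with
#' its 95% confidence interval and the standardized slope — the slope
#' divided by the outcome's standard deviation. Standardized slopes put
#' snRNA-seq totals and puncta counts on a common scale, so trends can be
#' compared across assays. This constructor is useful when only summary
#' statistics are available (e.g. a published slope and SD); fits from raw
#' data come from [standardized_slope()].
#'
#' @param beta slope per unit cell-type code.
#' @param ci_low,ci_high 95% confidence interval endpoints for `beta`.
#' @param sd_outcome sample standard deviation of the outcome (n-1
#'   denominator), must be positive.
#' @param n_obs number of observations behind the fit (`NA` if unknown).
#' @return a `trend_fit` object.
#' @export
#' @examples
#' # published slope -5.52 (95% CI -5.55, -5.49) with outcome SD 5.18
#' fit <- trend_fit(-5.52, -5.55, -5.49, 5.18)
#' round(fit$std_beta, 2)
trend_fit <- function(beta, ci_low, ci_high, sd_outcome, n_obs = NA_integer_) {
  if (!is.finite(sd_outcome) || sd_outcome <= 0) {
    treg_error("sd_outcome must be positive (constant outcome has no trend)")
  }
  if (!(ci_low <= beta && beta <= ci_high)) {
    treg_error("confidence interval [%g, %g] must bracket beta (%g)",
               ci_low, ci_high, beta)
  }
  structure(list(beta = beta, ci_low = ci_low, ci_high = ci_high,
                 sd_outcome = sd_outcome,
                 std_beta = beta / sd_outcome,
                 ci_std_low = ci_low / sd_outcome,
                 ci_std_high = ci_high / sd_outcome,
                 n_obs = n_obs),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Trend fit (n = %s)\n",
              ifelse(is.na(x$n_obs), "?", x$n_obs)))
  cat(sprintf("  beta     = %.4g  (95%% CI %.4g, %.4g)\n",
              x$beta, x$ci_low, x$ci_high))
  cat(sprintf("  sd       = %.4g\n", x$sd_outcome))
  cat(sprintf("  std beta = %.4g  (95%% CI %.4g, %.4g)\n",
              x$std_beta, x$ci_std_low, x$ci_std_high))
  invisible(x)
}

#' Standardized slope of an outcome over ordered cell types
#'
#' Encodes cell types as consecutive integer codes 1..K following the
#' supplied order (conventionally decreasing total RNA content, e.g.
#' Excit > Inhib > Oligo in cortex), fits ordinary least squares of the
#' outcome on the code with an intercept, and reports the slope with a
#' t-based 95% confidence interval (n-2 degrees of freedom) plus the
#' standardized slope `beta / sd(outcome)` with identically scaled CI
#' endpoints.
#'
#' @param outcome numeric vector, one value per unit (cell or nucleus).
#' @param cell_type character vector of labels, same length as `outcome`.
#' @param order character vector: the cell types in coding order; every
#'   observed label must appear in it.
#' @return a [trend_fit()] object.
#' @export
standardized_slope <- function(outcome, cell_type, order) {
  cell_type <- as.character(cell_type)
  if (length(outcome) != length(cell_type)) {
    treg_error("outcome and cell_type lengths differ")
  }
  unknown <- setdiff(unique(cell_type), order)
  if (length(unknown)) {
    treg_error("cell types not in the supplied order: %s",
               paste(unknown, collapse = ", "))
  }
  code <- match(cell_type, order)
  if (length(unique(code)) < 2L) {
    treg_error("need at least 2 distinct cell types to fit a trend")
  }
  s <- sd(outcome)
  if (!is.finite(s) || s == 0) {
    treg_error("constant outcome (sd = 0); trend undefined")
  }
  fit <- lm(outcome ~ code)
  beta <- unname(coef(fit)[2L])
  n <- length(outcome)
  # slope SE from residuals directly; summary.lm() would warn on the
  # legitimate zero-residual case, where the CI collapses onto beta
  sigma2 <- sum(stats::residuals(fit)^2) / (n - 2L)
  se <- sqrt(sigma2 / sum((code - mean(code))^2))
  tq <- qt(0.975, df = n - 2L)
  trend_fit(beta = beta, ci_low = beta - tq * se, ci_high = beta + tq * se,
            sd_outcome = s, n_obs = n)
}

#' Compare two trend fits on the standardized scale
#'
#' Reports the standardized slope of each fit, their absolute difference,
#' and — when a reference standardized slope is supplied (for instance the
#' snRNA-seq total-RNA trend) — which of the two lies closer to it.
#'
#' @param a,b `trend_fit` objects.
#' @param reference optional reference: a `trend_fit` or a bare
#'   standardized slope.
#' @return a `trend_comparison` list: `std_beta` (named length-2 vector),
#'   `abs_difference`, and when a reference is given `distance_to_reference`
#'   and `closer` (`"a"` or `"b"`).
#' @export
compare_trends <- function(a, b, reference = NULL) {
  stopifnot(is(a, "trend_fit"), is(b, "trend_fit"))
  sb <- c(a = a$std_beta, b = b$std_beta)
  out <- list(std_beta = sb, abs_difference = abs(sb[["a"]] - sb[["b"]]))
  if (!is.null(reference)) {
    ref <- if (is(reference, "trend_fit")) reference$std_beta else reference
    d <- abs(sb - ref)
    out$reference <- ref
    out$distance_to_reference <- d
    out$closer <- names(sb)[which.min(d)]
  }
  structure(out, class = "trend_comparison")
}

#' @export
print.trend_comparison <- function(x, ...) {
  cat(sprintf("std beta a = %.4g, b = %.4g (|diff| = %.4g)\n",
              x$std_beta[["a"]], x$std_beta[["b"]], x$abs_difference))
  if (!is.null(x$closer)) {
    cat(sprintf("closer to reference %.4g: %s\n", x$reference, x$closer))
  }
  invisible(x)
}

#' Serialize one or more trend fits to TSV
#'
#' @param fits a named list of `trend_fit` objects (names become the
#'   `outcome_name` column) or a single fit.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_trend_fits <- function(fits, path) {
  if (is(fits, "trend_fit")) fits <- list(outcome = fits)
  df <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(outcome_name = nm, beta = f$beta, ci_low = f$ci_low,
               ci_high = f$ci_high, sd = f$sd_outcome, std_beta = f$std_beta,
               ci_std_low = f$ci_std_low, ci_std_high = f$ci_std_high,
               n_obs = f$n_obs, stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
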