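# Quality-control filtering of the raw count matrix. "Expressed" always
# means a strictly positive count. All filters preserve the order of the
# retained rows/columns and report exactly what they removed.

new_filter_report <- function(genes_removed_min_cells = 0L,
                              genes_removed_high_expression = 0L,
                              cells_removed = 0L,
                              thresholds_used = list()) {
  structure(list(genes_removed_min_cells = genes_removed_min_cells,
                 genes_removed_high_expression = genes_removed_high_expression,
                 cells_removed = cells_removed,
                 thresholds_used = thresholds_used),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("QC filter report\n")
  cat("  genes removed (min-cells):      ", x$genes_removed_min_cells, "\n")
  cat("  genes removed (high expression):", x$genes_removed_high_expression, "\n")
  cat("  cells removed (quartile fence): ", x$cells_removed, "\n")
  invisible(x)
}

#' Remove genes expressed in too few cells
#'
#' A gene is retained only if it has a strictly positive count in at least
#' `min_cells` cells.
#'
#' @param X Cells x genes count matrix.
#' @param min_cells Minimum number of expressing cells (default 3).
#' @return A list with `matrix` (filtered) and `report` (a `"filter_report"`).
#' @export
filter_genes_min_cells <- function(X, min_cells = 3) {
  X <- as_expression_matrix(X)
  .check(is.numeric(min_cells) && min_cells >= 0, "min_cells must be >= 0")
  keep <- colSums(X > 0) >= min_cells
  .check(any(keep), "all genes removed by min-cells filter; relax min_cells (",
         min_cells, ")")
  list(matrix = X[, keep, drop = FALSE],
       report = new_filter_report(
         genes_removed_min_cells = sum(!keep),
         thresholds_used = list(min_cells = min_cells)))
}

#' Remove genes with extreme aggregate expression
#'
#' Computes a per-gene aggregate (total counts across cells by default) and
#' removes genes whose aggregate strictly exceeds the given quantile of the
#' aggregate distribution. This targets uniformly high expressors such as
#' housekeeping genes, which carry little between-cluster signal. Quantiles
#' use the linear-interpolation definition (R type 7); ties at the threshold
#' are retained.
#'
#' @param X Cells x genes count matrix.
#' @param quantile Quantile cutoff in (0, 1); default 0.75.
#' @param statistic Aggregate per gene: `"sum"` (default) or `"mean"`.
#' @return A list with `matrix` and `report`.
#' @export
filter_genes_high_expression <- function(X, quantile = 0.75,
                                         statistic = c("sum", "mean")) {
  X <- as_expression_matrix(X)
  statistic <- match.arg(statistic)
  .check(is.numeric(quantile) && quantile > 0 && quantile < 1,
         "quantile must lie strictly in (0, 1)")
  .check(ncol(X) >= 2, "high-expression filter needs at least 2 genes")
  agg <- if (statistic == "sum") colSums(X) else colMeans(X)
  thr <- stats::quantile(agg, probs = quantile, type = 7, names = FALSE)
  keep <- agg <= thr
  list(matrix = X[, keep, drop = FALSE],
       report = new_filter_report(
         genes_removed_high_expression = sum(!keep),
         thresholds_used = list(quantile = quantile, statistic = statistic,
                                cutoff_value = thr)))
}

#' Remove outlier cells by quartile fences
#'
#' For each cell, computes the total count (library size / UMI total) and the
#' number of detected genes. A cell is removed if either statistic falls
#' outside the Tukey fence \[Q1 - m*IQR, Q3 + m*IQR\] of its distribution
#' across cells, with `m = fence_multiplier`.
#'
#' @param X Cells x genes count matrix with at least 4 cells.
#' @param fence_multiplier Nonnegative fence width multiplier (default 1.5).
#' @return A list with `matrix` and `report`.
#' @export
filter_cells_quartile_fence <- function(X, fence_multiplier = 1.5) {
  X <- as_expression_matrix(X)
  .check(nrow(X) >= 4, "quartile fence filter needs at least 4 cells")
  .check(is.numeric(fence_multiplier) && fence_multiplier >= 0,
         "fence_multiplier must be >= 0")
  inside_fence <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    lo <- q[1] - fence_multiplier * iqr
    hi <- q[2] + fence_multiplier * iqr
    v >= lo & v <= hi
  }
  totals <- rowSums(X)
  detected <- rowSums(X > 0)
  keep <- inside_fence(totals) & inside_fence(detected)
  .check(any(keep), "all cells removed by quartile fence; relax fence_multiplier")
  list(matrix = X[keep, , drop = FALSE],
       report = new_filter_report(
         cells_removed = sum(!keep),
         thresholds_used = list(fence_multiplier = fence_multiplier)))
}

#' Library-size normalization with log transform
#'
#' Divides each cell's counts by its total, multiplies by `scale`, and
#' applies `log1p`. Run after cell filtering; a zero-total cell is an error.
#'
#' @param X Cells x genes count matrix with no all-zero cells.
#' @param scale Scale factor (default 1e4).
#' @return Normalized cells x genes matrix.
#' @export
library_normalize_log <- function(X, scale = 1e4) {
  X <- as_expression_matrix(X)
  totals <- rowSums(X)
  if (any(totals == 0)) {
    bad <- rownames(X)[totals == 0]
    .fail("zero-total cell(s): ", paste(utils::head(bad, 5), collapse = ", "),
          "; run cell filtering first")
  }
  log1p(X / totals * scale)
}

#' Full quality-control preprocessing
#'
#' Applies, in order: the minimum-cells gene filter, the quartile-fence cell
#' filter, and the high-expression gene filter (so that the high-expression
#' quantile is computed over QC-passed cells), then optional library-size
#' log-normalization.
#'
#' @param X Raw cells x genes count matrix.
#' @param min_cells Passed to [filter_genes_min_cells()].
#' @param high_quantile Passed to [filter_genes_high_expression()].
#' @param fence_multiplier Passed to [filter_cells_quartile_fence()].
#' @param normalize Apply [library_normalize_log()] to the filtered counts?
#' @param scale Normalization scale factor.
#' @return A list with `matrix` (filtered, optionally normalized), `counts`
#'   (filtered raw counts), and `report` (combined `"filter_report"`).
#' @export
preprocess <- function(X, min_cells = 3, high_quantile = 0.75,
                       fence_multiplier = 1.5, normalize = TRUE, scale = 1e4) {
  s1 <- filter_genes_min_cells(X, min_cells)
  s2 <- filter_cells_quartile_fence(s1$matrix, fence_multiplier)
  s3 <- filter_genes_high_expression(s2$matrix, high_quantile)
  report <- new_filter_report(
    genes_removed_min_cells = s1$report$genes_removed_min_cells,
    genes_removed_high_expression = s3$report$genes_removed_high_expression,
    cells_removed = s2$report$cells_removed,
    thresholds_used = c(s1$report$thresholds_used, s2$report$thresholds_used,
                        s3$report$thresholds_used,
                        list(order = "genes_min_cells, cells_quartile_fence, genes_high_expression")))
  out <- if (normalize) library_normalize_log(s3$matrix, scale) else s3$matrix
  list(matrix = out, counts = s3$matrix, report = report)
}
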