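# Readers and writers for the two supported on-disk matrix layouts:
# dense CSV/TSV (cells x genes by default) and 10x-style Matrix Market
# triplet directories (matrix.mtx genes x cells + barcodes.tsv +
# features.tsv / genes.tsv, transposed on read).

#' Read a dense CSV/TSV expression matrix
#'
#' Expects a header row of gene identifiers and a first column of cell
#' identifiers. Set `orientation = "genes_x_cells"` if rows are genes.
#'
#' @param path File path (`.csv` or tab-separated `.tsv`/`.txt`).
#' @param orientation `"cells_x_genes"` (default) or `"genes_x_cells"`.
#' @return A cells x genes numeric matrix with dimnames.
#' @export
read_counts_csv <- function(path, orientation = c("cells_x_genes", "genes_x_cells")) {
  orientation <- match.arg(orientation)
  .check(file.exists(path), "file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (orientation == "genes_x_cells") m <- t(m)
  as_expression_matrix(m)
}

#' Write a dense CSV expression matrix
#'
#' @param X Cells x genes matrix.
#' @param path Output file path.
#' @export
write_counts_csv <- function(X, path) {
  X <- as_expression_matrix(X)
  df <- data.frame(cell_id = rownames(X), X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a 10x-style Matrix Market directory
#'
#' Reads `matrix.mtx`, `barcodes.tsv` and `features.tsv` (or `genes.tsv`;
#' 1-, 2- or 3-column feature files are accepted, the first column is used
#' as the gene identifier). The on-disk matrix is genes x cells and is
#' transposed so the returned matrix is cells x genes.
#'
#' @param dir Directory containing the three files.
#' @return A cells x genes numeric matrix with dimnames.
#' @export
read_counts_mtx <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  .check(file.exists(mtx), "matrix.mtx not found in ", dir)
  feats <- file.path(dir, c("features.tsv", "genes.tsv"))
  feats <- feats[file.exists(feats)][1]
  .check(!is.na(feats), "features.tsv / genes.tsv not found in ", dir)
  barcodes <- file.path(dir, "barcodes.tsv")
  .check(file.exists(barcodes), "barcodes.tsv not found in ", dir)
  m <- as.matrix(Matrix::readMM(mtx))
  fid <- utils::read.table(feats, sep = "\t", stringsAsFactors = FALSE)[[1]]
  bid <- utils::read.table(barcodes, sep = "\t", stringsAsFactors = FALSE)[[1]]
  .check(nrow(m) == length(fid), "matrix.mtx row count does not match features file")
  .check(ncol(m) == length(bid), "matrix.mtx column count does not match barcodes file")
  m <- t(m)
  dimnames(m) <- list(bid, fid)
  as_expression_matrix(m)
}

#' Write a 10x-style Matrix Market directory
#'
#' @param X Cells x genes matrix; written transposed (genes x cells) with
#'   `barcodes.tsv` and `features.tsv` alongside.
#' @param dir Output directory (created if missing).
#' @export
write_counts_mtx <- function(X, dir) {
  X <- as_expression_matrix(X)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(t(X), sparse = TRUE), file.path(dir, "matrix.mtx"))
  writeLines(rownames(X), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(X), file.path(dir, "features.tsv"))
  invisible(dir)
}

#' Read cluster labels from a CSV file
#'
#' Accepts either a one-column file of labels or a two-column file with
#' `cell_id` first and the label second (header optional for one column).
#'
#' @param path CSV file path.
#' @return A vector of labels; named by cell id when ids are present.
#' @export
read_labels_csv <- function(path) {
  .check(file.exists(path), "file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) >= 2) {
    labs <- df[[2]]
    names(labs) <- as.character(df[[1]])
  } else {
    labs <- df[[1]]
  }
  labs
}

#' Export a cell graph
#'
#' Writes the weighted adjacency as an edge-list TSV (`cell_i`, `cell_j`,
#' `weight`, upper triangle only) and as a sparse Matrix Market file.
#'
#' @param graph A `"cell_graph"` object.
#' @param dir Output directory.
#' @export
write_cell_graph <- function(graph, dir) {
  .check(inherits(graph, "cell_graph"), "graph must be a cell_graph")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  A <- graph$adjacency
  idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  el <- data.frame(cell_i = graph$cell_ids[idx[, 1]],
                   cell_j = graph$cell_ids[idx[, 2]],
                   weight = A[idx])
  utils::write.table(el, file.path(dir, "edges.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  Matrix::writeMM(Matrix::Matrix(A, sparse = TRUE), file.path(dir, "adjacency.mtx"))
  invisible(dir)
}
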