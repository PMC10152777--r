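# Construction of the auxiliary cell graph: Pearson similarity between
# cells, Network Enhancement denoising of the similarity network, and
# k-nearest-neighbor sparsification into the adjacency used by the
# attention layers.

#' Pearson correlation similarity between cells
#'
#' Entry (i, j) is the Pearson correlation of cell i's and cell j's gene
#' expression vectors; the diagonal is set to 0 (self-similarity carries no
#' information and Network Enhancement expects a zero diagonal).
#'
#' @param X Cells x genes matrix with at least 2 genes; every cell must have
#'   nonzero variance across genes.
#' @return A symmetric cells x cells similarity matrix with zero diagonal.
#' @export
pearson_similarity <- function(X) {
  if (inherits(X, "Matrix")) X <- as.matrix(X)
  .check(is.matrix(X) && is.numeric(X), "X must be a numeric matrix")
  .check(all(is.finite(X)), "X contains non-finite values")
  if (is.null(rownames(X))) rownames(X) <- paste0("cell_", seq_len(nrow(X)))
  .check(ncol(X) >= 2, "need at least 2 genes to correlate cells")
  v <- apply(X, 1, stats::var)
  if (any(v == 0)) {
    .fail("zero-variance cell(s): ",
          paste(utils::head(rownames(X)[v == 0], 5), collapse = ", "),
          "; drop them before building the graph")
  }
  S <- stats::cor(t(X))
  S <- (S + t(S)) / 2
  diag(S) <- 0
  S
}

#' Map a similarity matrix to nonnegative weights
#'
#' Network Enhancement is defined on nonnegative affinities. `"clip"` sets
#' negative entries to zero (default); `"minmax"` affinely rescales all
#' off-diagonal entries to \[0, 1\], preserving their order.
#'
#' @param S Symmetric similarity matrix.
#' @param policy `"clip"` or `"minmax"`.
#' @return Symmetric nonnegative matrix, zero diagonal preserved.
#' @export
shift_to_nonnegative <- function(S, policy = c("clip", "minmax")) {
  policy <- match.arg(policy)
  .check(is.matrix(S) && isSymmetric(unname(S), tol = 1e-8), "S must be symmetric")
  if (policy == "clip") {
    S[S < 0] <- 0
  } else {
    off <- row(S) != col(S)
    rng <- range(S[off])
    if (rng[2] > rng[1]) {
      S[off] <- (S[off] - rng[1]) / (rng[2] - rng[1])
    } else {
      S[off] <- 0
    }
  }
  (S + t(S)) / 2
}

# Symmetric Sinkhorn-Knopp scaling to a doubly stochastic matrix:
# repeatedly divide by sqrt of row sums on both sides. Preserves symmetry;
# converges for symmetric nonnegative matrices with support.
sinkhorn_scale <- function(W, tol = 1e-6, max_iter = 1000) {
  n <- nrow(W)
  rs <- rowSums(W)
  .check(all(rs > 0), "disconnected node(s) with zero similarity row; ",
         "cannot scale to doubly stochastic")
  for (i in seq_len(max_iter)) {
    d <- sqrt(rowSums(W))
    W <- W / (d %o% d)
    err <- max(abs(rowSums(W) - 1), abs(colSums(W) - 1))
    if (err < tol) return(W)
  }
  .fail("Sinkhorn scaling did not converge after ", max_iter,
        " iterations (residual ", format(err), ")")
}

# Per-row top-k localization: keep each row's k largest off-diagonal
# entries (ties at the k-th value broken toward the smaller column index),
# then symmetrize by averaging.
localize_topk <- function(S, k) {
  n <- nrow(S)
  P <- matrix(0, n, n, dimnames = dimnames(S))
  for (i in seq_len(n)) {
    row <- S[i, ]
    row[i] <- -Inf
    ord <- order(-row, seq_len(n))
    keep <- ord[seq_len(min(k, n - 1))]
    P[i, keep] <- S[i, keep]
  }
  (P + t(P)) / 2
}

#' Network Enhancement denoising of a similarity network
#'
#' Amplifies strong within-community edges relative to weak between-
#' community edges by a diffusion on the doubly stochastic scaling of a
#' locally restricted similarity matrix. Concretely: (i) each node is
#' restricted to its `k_ne` strongest neighbors; (ii) the localized matrix
#' is scaled to doubly stochastic form `T` by symmetric Sinkhorn iteration;
#' (iii) the fixed point of `W <- alpha * T^order %*% W + (1 - alpha) * T`
#' is computed by iteration, which maps each eigenvalue `l` of `T` to
#' `(1 - alpha) * l / (1 - alpha * l^order)` while leaving eigenvectors
#' unchanged, enlarging the top eigengap; (iv) node degrees of the localized
#' input are re-applied and the result symmetrized.
#'
#' @param S Symmetric nonnegative similarity matrix, zero diagonal, at least
#'   2 nodes, no all-zero rows after localization.
#' @param k_ne Neighborhood size for localization; default
#'   `min(20, ceiling(n / 10))`, at least 1.
#' @param alpha Diffusion retention in (0, 1); default 0.9.
#' @param order Diffusion order (positive integer); default 2.
#' @param tol Convergence tolerance on the fixed-point residual.
#' @param max_iter Maximum diffusion iterations.
#' @return Symmetric nonnegative denoised similarity matrix, zero diagonal.
#' @export
network_enhancement <- function(S, k_ne = NULL, alpha = 0.9, order = 2,
                                tol = 1e-6, max_iter = 1000) {
  .check(is.matrix(S) && nrow(S) == ncol(S) && nrow(S) >= 2,
         "S must be a square matrix with at least 2 nodes")
  .check(max(abs(S - t(S))) <= 1e-8, "S must be symmetric")
  .check(all(S >= 0), "S must be nonnegative (apply shift_to_nonnegative first)")
  .check(is.numeric(alpha) && alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  .check(.is_count(order) && order >= 1, "order must be a positive integer")
  n <- nrow(S)
  if (is.null(k_ne)) k_ne <- max(1L, min(20L, ceiling(n / 10)))
  .check(.is_count(k_ne) && k_ne >= 1, "k_ne must be a positive integer")
  diag(S) <- 0

  P <- localize_topk(S, k_ne)
  degrees <- rowSums(abs(P))
  .check(all(degrees > 0), "disconnected node(s) after localization; increase k_ne")
  T_ds <- sinkhorn_scale(P, tol = 1e-6, max_iter = 1000)

  M <- T_ds
  if (order > 1) for (i in seq_len(order - 1)) M <- M %*% T_ds
  W <- T_ds
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    W_new <- alpha * (M %*% W) + (1 - alpha) * T_ds
    res <- max(abs(W_new - W))
    W <- W_new
    if (res < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    .fail("network enhancement diffusion did not converge after ", max_iter,
          " iterations (residual ", format(res), ")")
  }
  W <- (W + t(W)) / 2

  # Redistribute the (small) diagonal mass and restore input degrees.
  d <- diag(W)
  W <- W * (1 - diag(n))
  W <- W / pmax(1 - d, .Machine$double.eps)
  W <- degrees * W
  W[W < 0] <- 0
  W <- (W + t(W)) / 2
  diag(W) <- 0
  dimnames(W) <- dimnames(S)
  W
}

#' Sparsify a similarity matrix into a k-nearest-neighbor cell graph
#'
#' Keeps, per row, the k largest off-diagonal weights (ties at the k-th
#' value broken toward the smaller column index) and zeroes the rest, then
#' symmetrizes: `"union"` keeps an edge if either endpoint selected it
#' (weight = max), `"intersection"` only if both did (weight = min).
#'
#' @param S Similarity matrix (typically the Network Enhancement output).
#' @param k Neighbors per node, `1 <= k < n`.
#' @param symmetrize `"union"` (default) or `"intersection"`.
#' @return A `"cell_graph"` object with fields `adjacency` (symmetric
#'   nonnegative matrix, zero diagonal), `k`, `symmetrize`, `cell_ids`.
#' @export
knn_sparsify <- function(S, k, symmetrize = c("union", "intersection")) {
  symmetrize <- match.arg(symmetrize)
  .check(is.matrix(S) && nrow(S) == ncol(S), "S must be square")
  n <- nrow(S)
  .check(.is_count(k) && k >= 1 && k < n, "k must satisfy 1 <= k < n_cells")
  A <- matrix(0, n, n, dimnames = dimnames(S))
  for (i in seq_len(n)) {
    row <- S[i, ]
    row[i] <- -Inf
    keep <- order(-row, seq_len(n))[seq_len(k)]
    A[i, keep] <- S[i, keep]
  }
  A <- if (symmetrize == "union") pmax(A, t(A)) else pmin(A, t(A))
  A[A < 0] <- 0
  diag(A) <- 0
  ids <- rownames(S)
  if (is.null(ids)) ids <- paste0("cell_", seq_len(n))
  structure(list(adjacency = A, k = as.integer(k), symmetrize = symmetrize,
                 cell_ids = ids),
            class = "cell_graph")
}

#' @export
print.cell_graph <- function(x, ...) {
  n <- nrow(x$adjacency)
  ne <- sum(x$adjacency[upper.tri(x$adjacency)] > 0)
  cat("cell_graph:", n, "cells,", ne, "edges (k =", x$k,
      ", symmetrize =", x$symmetrize, ")\n")
  invisible(x)
}

#' Build the denoised cell graph from a preprocessed matrix
#'
#' Convenience wrapper chaining [pearson_similarity()],
#' [shift_to_nonnegative()], [network_enhancement()] and [knn_sparsify()].
#' When the expected cluster count `K` is supplied, the default KNN `k` is
#' `ceiling(n / (2 * K))` clipped to \[3, 30\] (else 15), capped at `n - 1`.
#'
#' @param X Preprocessed cells x genes matrix.
#' @param K Optional expected cluster count (sets the default `knn_k`).
#' @param knn_k Neighbors per node; overrides the default.
#' @param k_ne,alpha,order Passed to [network_enhancement()].
#' @param negative_policy Passed to [shift_to_nonnegative()].
#' @param symmetrize Passed to [knn_sparsify()].
#' @return A `"cell_graph"` object.
#' @export
build_cell_graph <- function(X, K = NULL, knn_k = NULL, k_ne = NULL,
                             alpha = 0.9, order = 2,
                             negative_policy = c("clip", "minmax"),
                             symmetrize = c("union", "intersection")) {
  n <- nrow(X)
  if (is.null(knn_k)) {
    knn_k <- if (is.null(K)) 15L else min(30L, max(3L, ceiling(n / (2 * K))))
    knn_k <- min(knn_k, n - 1L)
  }
  S <- pearson_similarity(X)
  S <- shift_to_nonnegative(S, match.arg(negative_policy))
  W <- network_enhancement(S, k_ne = k_ne, alpha = alpha, order = order)
  knn_sparsify(W, k = as.integer(knn_k), symmetrize = match.arg(symmetrize))
}
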