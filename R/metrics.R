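# Clustering agreement metrics: adjusted Rand index and normalized mutual
# information, both computed from the contingency table of two partitions.

#' Contingency table of two partitions
#'
#' @param labels_a,labels_b Label vectors of equal length (any atomic type).
#' @return A `"contingency_table"`: list with `n_ij` (r x c integer
#'   matrix), `a_i`, `b_j` (marginals) and `n` (total).
#' @export
contingency <- function(labels_a, labels_b) {
  .check(length(labels_a) == length(labels_b),
         "label vectors differ in length (", length(labels_a), " vs ",
         length(labels_b), ")")
  .check(length(labels_a) >= 1, "empty label vectors")
  tab <- table(factor(labels_a), factor(labels_b))
  n_ij <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                 dimnames = dimnames(tab))
  structure(list(n_ij = n_ij,
                 a_i = as.integer(rowSums(n_ij)),
                 b_j = as.integer(colSums(n_ij)),
                 n = sum(n_ij)),
            class = "contingency_table")
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions:
#' `(sum_ij C(n_ij,2) - E) / (max - E)` with
#' `E = sum_i C(a_i,2) * sum_j C(b_j,2) / C(n,2)` and
#' `max = (sum_i C(a_i,2) + sum_j C(b_j,2)) / 2`.
#' Equals 1 for identical partitions (up to relabeling), has expectation
#' ~0 for independent partitions, and is symmetric in its arguments.
#'
#' @param labels_true,labels_pred Label vectors of equal length.
#' @return A scalar in \[-1, 1\].
#' @export
ari <- function(labels_true, labels_pred) {
  ct <- contingency(labels_true, labels_pred)
  comb2 <- function(m) m * (m - 1) / 2
  sum_ij <- sum(comb2(ct$n_ij))
  sum_a <- sum(comb2(ct$a_i))
  sum_b <- sum(comb2(ct$b_j))
  n2 <- comb2(ct$n)
  if (n2 == 0) return(1)
  # cleared of the 1/C(n,2) factor so every term is an exact integer-valued
  # double and small examples come out exact
  num <- sum_ij * n2 - sum_a * sum_b
  den <- (sum_a + sum_b) / 2 * n2 - sum_a * sum_b
  if (den == 0) return(1)  # both partitions trivial (all-singletons or
                           # single-cluster on both sides)
  num / den
}

# Mutual information and entropies (nats) from a contingency table.
mi_entropies <- function(ct) {
  n <- ct$n
  p <- ct$n_ij / n
  px <- ct$a_i / n
  py <- ct$b_j / n
  pos <- p > 0
  pxy <- outer(px, py)
  I <- sum(p[pos] * log(p[pos] / pxy[pos]))
  Hx <- -sum(px[px > 0] * log(px[px > 0]))
  Hy <- -sum(py[py > 0] * log(py[py > 0]))
  list(I = max(0, I), Hx = Hx, Hy = Hy)
}

#' Normalized mutual information
#'
#' Mutual information between two partitions, computed from their
#' contingency table and normalized to \[0, 1\]. The default `"mean"`
#' normalization divides by the arithmetic mean of the two marginal
#' entropies, `2 I / (H(X) + H(Y))`, which equals 1 for identical
#' partitions. The `"sum_log_k"` variant divides by
#' `2 (log K + log c)` (K, c = numbers of clusters in each partition); it
#' does not reach 1 for a perfect clustering and is provided for
#' comparability only.
#'
#' @param labels_true,labels_pred Label vectors of equal length.
#' @param normalization `"mean"` (default) or `"sum_log_k"`.
#' @return A scalar in \[0, 1\].
#' @export
nmi <- function(labels_true, labels_pred,
                normalization = c("mean", "sum_log_k")) {
  normalization <- match.arg(normalization)
  ct <- contingency(labels_true, labels_pred)
  e <- mi_entropies(ct)
  if (normalization == "mean") {
    denom <- e$Hx + e$Hy
    if (denom == 0) return(1)  # both partitions constant, hence identical
    return(2 * e$I / denom)
  }
  K <- nrow(ct$n_ij); c_ <- ncol(ct$n_ij)
  denom <- 2 * (log(K) + log(c_))
  if (denom == 0) return(0)
  e$I / denom
}

#' Metrics report for a predicted clustering
#'
#' @param labels_true,labels_pred Label vectors of equal length.
#' @param normalization NMI normalization (see [nmi()]).
#' @return A list with `ari`, `nmi`, `n_cells`, `K_true`, `K_pred`,
#'   `normalization`, suitable for JSON export.
#' @export
metrics_report <- function(labels_true, labels_pred,
                           normalization = c("mean", "sum_log_k")) {
  normalization <- match.arg(normalization)
  list(ari = ari(labels_true, labels_pred),
       nmi = nmi(labels_true, labels_pred, normalization),
       n_cells = length(labels_true),
       K_true = length(unique(labels_true)),
       K_pred = length(unique(labels_pred)),
       normalization = normalization)
}
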