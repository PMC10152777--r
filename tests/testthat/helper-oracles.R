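# Independent oracles used to validate the package's metric and graph
# computations. These deliberately use a different route than the
# implementation (pair counting instead of contingency binomials; entropy
# identities instead of the direct mutual-information sum).

# Adjusted Rand index by brute-force pair counting over all element pairs.
oracle_ari_pairs <- function(a, b) {
  n <- length(a)
  s11 <- s10 <- s01 <- s00 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) s11 <- s11 + 1
      else if (sa && !sb) s10 <- s10 + 1
      else if (!sa && sb) s01 <- s01 + 1
      else s00 <- s00 + 1
    }
  }
  denom <- (s11 + s10) * (s10 + s00) + (s11 + s01) * (s01 + s00)
  if (denom == 0) return(1)
  2 * (s11 * s00 - s10 * s01) / denom
}

# Mutual information (nats) via the entropy identity I = H(X) + H(Y) - H(X,Y),
# i.e. the joint/conditional entropy route, computed from scratch tabulations.
oracle_mi_entropy <- function(a, b) {
  ent <- function(x) {
    p <- table(x) / length(x)
    -sum(p * log(p))
  }
  ent(a) + ent(b) - ent(paste(a, b, sep = "\r"))
}

# Direct mutual information from the joint distribution, sum p*log(p/(px*py)).
oracle_mi_direct <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p); py <- colSums(p)
  pos <- p > 0
  sum(p[pos] * log(p[pos] / outer(px, py)[pos]))
}

random_partition_pair <- function(n, K) {
  list(a = sample.int(K, n, replace = TRUE),
       b = sample.int(K, n, replace = TRUE))
}

# A 20-cell x 50-gene QC fixture with exactly 5 genes expressed in < 3
# cells, 2 extreme-aggregate (housekeeping-like) genes, and 1 outlier cell:
# expected filter counts (5, 2, 1), expected output 19 x 43.
toy_qc_matrix <- function() {
  X <- matrix(5, nrow = 20, ncol = 50)
  colnames(X) <- paste0("g", 1:50)
  rownames(X) <- paste0("c", 1:20)
  X[, 44:45] <- 1000                 # housekeeping-like, high in every cell
  X[, 46:50] <- 0                    # sparse genes: expressed in 2 cells only
  X[1:2, 46:50] <- 1
  X[20, 1:43] <- 100                 # outlier cell: extreme library size
  X
}

# Two-community similarity matrix with cross-block noise, for the network
# enhancement spectral checks.
two_block_similarity <- function(n = 40, strength = c(0.6, 1), noise = 0.05,
                                 seed = 1) {
  stopifnot(n %% 2 == 0)
  scea:::with_seed(seed, {
    half <- n / 2
    S <- matrix(stats::runif(n * n, 0, noise), n)
    blk <- function(m) matrix(stats::runif(m * m, strength[1], strength[2]), m)
    S[1:half, 1:half] <- blk(half)
    S[(half + 1):n, (half + 1):n] <- blk(half)
    S <- (S + t(S)) / 2
    diag(S) <- 0
    S
  })
}

# Top eigengap (l1 - l2) of the doubly stochastic scaling of a similarity
# matrix: the normalization under which the diffusion's eigenvalue map is
# exact.
normalized_eigengap <- function(S) {
  T_ds <- scea:::sinkhorn_scale(S)
  ev <- sort(eigen(T_ds, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev[1] - ev[2]
}

# Small well-separated simulation reused across network tests.
small_separable_sim <- function(n = 120, g = 300, K = 3, seed = 5) {
  generate_counts(synthetic_spec(n, g, K, de_fraction = 0.3,
                                 log_fold_change = 2.5, dropout_rate = 0.3,
                                 dispersion = 0.3, seed = seed))
}
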