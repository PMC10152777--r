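test_that("pearson similarity matches the covariance formula and flags degenerate cells", {
  X <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 2, 1))
  S <- pearson_similarity(X)
  expect_equal(S["a", "b"], 1)
  expect_equal(S["a", "c"], -1)
  expect_identical(diag(S), c(a = 0, b = 0, c = 0))

  set.seed(1)
  R <- matrix(rnorm(5 * 20), 5, 20)
  S <- pearson_similarity(R)
  # independent oracle: direct covariance / sd formula per pair
  for (i in 1:4) for (j in (i + 1):5) {
    x <- R[i, ]; y <- R[j, ]
    r <- mean((x - mean(x)) * (y - mean(y))) /
      sqrt(mean((x - mean(x))^2) * mean((y - mean(y))^2))
    expect_equal(S[i, j], r, tolerance = 1e-12)
  }

  Xflat <- rbind(c(1, 1, 1), c(1, 2, 3))
  expect_error(pearson_similarity(Xflat), "zero-variance")
})

test_that("negative-value policies preserve symmetry and order", {
  S <- rbind(c(0, -0.3, 0.5), c(-0.3, 0, 0.9), c(0.5, 0.9, 0))
  clip <- shift_to_nonnegative(S, "clip")
  expect_identical(clip[1, 2], 0)
  expect_identical(clip[1, 3], 0.5)
  expect_identical(clip, t(clip))

  mm <- shift_to_nonnegative(S, "minmax")
  off <- mm[row(mm) != col(mm)]
  expect_equal(range(off), c(0, 1))
  expect_identical(order(S[upper.tri(S)]), order(mm[upper.tri(mm)]))

  Spos <- abs(S)
  expect_identical(shift_to_nonnegative(Spos, "clip"), Spos)
})

test_that("network enhancement: doubly stochastic core, symmetry, eigengap growth", {
  S <- two_block_similarity(40)
  # the internal scaling reaches row and column sums of 1
  T_ds <- scea:::sinkhorn_scale(scea:::localize_topk(S, 25))
  expect_lt(max(abs(rowSums(T_ds) - 1)), 1e-6)
  expect_lt(max(abs(colSums(T_ds) - 1)), 1e-6)

  W <- network_enhancement(S, k_ne = 25)
  expect_lt(max(abs(W - t(W))), 1e-8)
  expect_true(all(W >= 0))
  expect_gt(normalized_eigengap(W), normalized_eigengap(S))
})

test_that("network enhancement preserves leading eigenvectors", {
  S <- two_block_similarity(30, seed = 4)
  T_ds <- scea:::sinkhorn_scale(scea:::localize_topk(S, 20))
  W <- network_enhancement(S, k_ne = 20)
  U_in <- eigen(T_ds, symmetric = TRUE)$vectors[, 1:3]
  U_out <- eigen(scea:::sinkhorn_scale(W), symmetric = TRUE)$vectors[, 1:3]
  expect_true(all(abs(colSums(U_in * U_out)) >= 0.99))
})

test_that("network enhancement rejects degenerate input", {
  expect_error(network_enhancement(matrix(0, 1, 1)), "at least 2")
  S <- matrix(0, 4, 4)  # fully disconnected
  expect_error(network_enhancement(S, k_ne = 2), "disconnected")
  A <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(network_enhancement(A), "symmetric")
  expect_error(network_enhancement(-two_block_similarity(10)), "nonnegative")
})

test_that("knn sparsification keeps the k strongest edges with the stated tie rule", {
  S <- rbind(c(0, 0.9, 0.5, 0.1),
             c(0.9, 0, 0.5, 0.5),
             c(0.5, 0.5, 0, 0.2),
             c(0.1, 0.5, 0.2, 0))
  g <- knn_sparsify(S, k = 2, symmetrize = "intersection")
  # row 2 has a tie at 0.5 between columns 3 and 4: lower index wins
  expect_identical(g$adjacency[2, 3], 0.5)
  expect_identical(g$adjacency[2, 4], 0)

  # k = n - 1 reproduces the input minus its diagonal
  full <- knn_sparsify(S, k = 3)
  expect_equal(full$adjacency, S)

  set.seed(7)
  R <- abs(matrix(rnorm(400), 20)); R <- (R + t(R)) / 2; diag(R) <- 0
  g <- knn_sparsify(R, k = 5, symmetrize = "union")
  A <- g$adjacency
  expect_identical(A, t(A))
  nz <- rowSums(A != 0)
  expect_true(all(nz >= 5 & nz <= 19))
  # never invents weight: every kept weight exists at the same spot in R
  expect_true(all(A[A != 0] == R[A != 0]))
})

test_that("graph pipeline is deterministic in its inputs", {
  sim <- small_separable_sim()
  X <- preprocess(sim$counts)$matrix
  g1 <- build_cell_graph(X, K = 3)
  g2 <- build_cell_graph(X, K = 3)
  expect_identical(g1$adjacency, g2$adjacency)
  expect_identical(g1$k, g2$k)
})
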