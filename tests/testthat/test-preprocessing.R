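test_that("min-cells filter keeps exactly the genes expressed in enough cells", {
  X <- matrix(0, 4, 3, dimnames = list(paste0("c", 1:4), paste0("g", 1:3)))
  X[, 1] <- c(1, 2, 3, 4)   # expressed in 4 cells
  X[1:2, 2] <- 1            # expressed in 2 cells
  # g3 all zero
  res <- filter_genes_min_cells(X, min_cells = 3)
  expect_identical(colnames(res$matrix), "g1")
  expect_identical(res$report$genes_removed_min_cells, 2L)

  X[1:3, 2] <- 1            # boundary: exactly 3 cells is kept
  res <- filter_genes_min_cells(X, min_cells = 3)
  expect_identical(colnames(res$matrix), c("g1", "g2"))

  # matches a brute-force nonzero-count scan on random input
  set.seed(1)
  R <- matrix(rbinom(50 * 200, 1, 0.05) * rpois(50 * 200, 4), 50, 200)
  keep_oracle <- which(apply(R, 2, function(col) sum(col > 0)) >= 3)
  res <- filter_genes_min_cells(R, 3)
  expect_identical(unname(res$matrix), R[, keep_oracle])

  expect_error(filter_genes_min_cells(matrix(0, 3, 2), 1), "relax")
})

test_that("high-expression filter removes genes strictly above the quantile", {
  # aggregates 1, 2, 3, 100: only the 100 gene exceeds the interpolated Q3
  X <- rbind(c(1, 2, 3, 100))
  q3 <- unname(stats::quantile(c(1, 2, 3, 100), 0.75))  # oracle: type-7 interpolation
  res <- filter_genes_high_expression(X, 0.75)
  expect_identical(ncol(res$matrix), 3L)
  expect_identical(res$report$genes_removed_high_expression, 1L)
  expect_equal(res$report$thresholds_used$cutoff_value, q3)

  # ties at the threshold are retained
  Xeq <- matrix(2, 5, 6)
  res <- filter_genes_high_expression(Xeq, 0.75)
  expect_identical(ncol(res$matrix), 6L)

  # extreme quantile removes at most the single largest gene
  set.seed(2)
  Xr <- matrix(rpois(40 * 10, 5), 40, 10)
  res <- filter_genes_high_expression(Xr, 0.999)
  expect_gte(ncol(res$matrix), 9L)
  expect_error(filter_genes_high_expression(matrix(1, 3, 1)), "2 genes")
})

test_that("quartile fence removes only genuine outlier cells", {
  X <- matrix(1, 9, 10)
  X[9, ] <- 100             # totals (10,...,10,1000)
  res <- filter_cells_quartile_fence(X, 1.5)
  expect_identical(nrow(res$matrix), 8L)
  expect_identical(res$report$cells_removed, 1L)

  # all-identical cells: IQR = 0, everything sits on the fence and stays
  res <- filter_cells_quartile_fence(matrix(3, 6, 4), 1.5)
  expect_identical(nrow(res$matrix), 6L)

  # an enormous multiplier keeps every cell (nonzero IQR so the fence scales)
  Xv <- matrix(rep(1:9, each = 10), 9, 10, byrow = TRUE)
  Xv[9, ] <- 1000
  res <- filter_cells_quartile_fence(Xv, 1e9)
  expect_identical(nrow(res$matrix), 9L)
})

test_that("library normalization matches the element-wise formula", {
  X <- rbind(c(0, 0, 10))
  expect_equal(unname(library_normalize_log(X, scale = 10)),
               rbind(c(0, 0, log(11))))
  set.seed(3)
  R <- matrix(rpois(20 * 15, 3) + 1, 20, 15)
  out <- library_normalize_log(R, 1e4)
  oracle <- t(apply(R, 1, function(r) log1p(r / sum(r) * 1e4)))
  expect_equal(unname(out), oracle, tolerance = 1e-12)

  bad <- matrix(c(1, 0, 2, 0), 2, 2)
  bad[1, ] <- 0
  expect_error(library_normalize_log(bad), "zero-total")
})

test_that("filters are idempotent and commute with permutations", {
  set.seed(4)
  X <- matrix(rbinom(30 * 80, 1, 0.3) * rpois(30 * 80, 6), 30, 80,
              dimnames = list(paste0("c", 1:30), paste0("g", 1:80)))
  # the min-cells filter is idempotent: removing a gene cannot change any
  # other gene's expressing-cell count. (The quantile-based filters are
  # deliberately not: their thresholds are recomputed from the current
  # dataset, so a second application can tighten further.)
  once <- filter_genes_min_cells(X, 3)$matrix
  expect_identical(filter_genes_min_cells(once, 3)$matrix, once)
  # quantile filters ARE idempotent at fence extremes, where the threshold
  # cannot move through remaining values
  keep_all <- filter_cells_quartile_fence(X, 1e9)$matrix
  expect_identical(filter_cells_quartile_fence(keep_all, 1e9)$matrix, keep_all)
  # permuting cells and genes permutes the output identically
  pc <- sample(30); pg <- sample(80)
  perm <- X[pc, pg]
  a <- filter_genes_min_cells(perm, 3)$matrix
  b <- filter_genes_min_cells(X, 3)$matrix
  expect_setequal(colnames(a), colnames(b))
  expect_identical(a, perm[, colnames(perm) %in% colnames(b), drop = FALSE])
})

test_that("combined preprocessing reconstructs input dimensions from the report", {
  X <- toy_qc_matrix()
  res <- preprocess(X, normalize = FALSE)
  rep <- res$report
  expect_identical(dim(res$matrix), c(19L, 43L))
  expect_identical(rep$genes_removed_min_cells, 5L)
  expect_identical(rep$genes_removed_high_expression, 2L)
  expect_identical(rep$cells_removed, 1L)
  expect_identical(nrow(res$matrix) + rep$cells_removed, nrow(X))
  expect_identical(ncol(res$matrix) + rep$genes_removed_min_cells +
                     rep$genes_removed_high_expression, ncol(X))
})
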