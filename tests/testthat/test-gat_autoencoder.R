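# Helpers: a small random graph + features for attention-layer contracts.
random_graph <- function(n, k = 4, seed = 1) {
  scea:::with_seed(seed, {
    S <- abs(matrix(rnorm(n * n), n)); S <- (S + t(S)) / 2; diag(S) <- 0
    knn_sparsify(S, k)
  })
}

test_that("attention maps are row-stochastic on the graph support", {
  n <- 30
  g <- random_graph(n)
  H <- matrix(rnorm(n * 6), n)
  res <- attention_layer(H, g, n_heads = 4, out_dim = 3, seed = 2)
  support <- g$adjacency != 0; diag(support) <- TRUE
  for (A in res$attention) {
    expect_lt(max(abs(rowSums(A) - 1)), 1e-6)
    expect_true(all(A >= 0))
    expect_true(all(A[!support] == 0))
  }
  expect_identical(dim(res$out), c(30L, 12L))  # concat merge: heads * out_dim
})

test_that("a node with only a self-loop attends to itself with weight 1", {
  S <- matrix(0, 5, 5)
  S[1, 2] <- S[2, 1] <- 1; S[2, 3] <- S[3, 2] <- 1; S[4, 5] <- S[5, 4] <- 1
  g <- structure(list(adjacency = S, k = 1L, symmetrize = "union",
                      cell_ids = paste0("c", 1:5)), class = "cell_graph")
  # rewire so node 3 is isolated (no edges at all)
  g$adjacency[3, ] <- 0; g$adjacency[, 3] <- 0
  H <- matrix(rnorm(20), 5)
  res <- attention_layer(H, g, n_heads = 2, out_dim = 2, seed = 0)
  for (A in res$attention) expect_identical(A[3, 3], 1)
})

test_that("identical neighbors with identical features share attention equally", {
  S <- matrix(0, 3, 3)
  S[1, 2] <- S[2, 1] <- S[1, 3] <- S[3, 1] <- 1
  g <- structure(list(adjacency = S, k = 2L, symmetrize = "union",
                      cell_ids = paste0("c", 1:3)), class = "cell_graph")
  H <- rbind(c(1, 2), c(1, 2), c(1, 2))  # all nodes identical
  res <- attention_layer(H, g, n_heads = 3, out_dim = 2, seed = 5)
  for (A in res$attention) {
    expect_equal(unname(A[1, ]), c(1, 1, 1) / 3, tolerance = 1e-12)
  }
})

test_that("node permutation equivariance holds for the full autoencoder", {
  n <- 15
  g <- random_graph(n, k = 3, seed = 9)
  E <- matrix(rnorm(n * 8), n)
  cfg <- gat_config(input_dim = 8, hidden_dim = 6, latent_dim = 3,
                    n_heads = 2, epochs = 0, seed = 4)
  params <- scea:::with_seed(4, scea:::gat_init_params(cfg))
  sup <- scea:::gat_support(g)
  fw <- scea:::gat_ae_forward(params, E, sup, cfg)

  p <- scea:::with_seed(1, sample(n))
  gp <- g; gp$adjacency <- g$adjacency[p, p]
  fw_p <- scea:::gat_ae_forward(params, E[p, ], scea:::gat_support(gp), cfg)
  expect_equal(fw_p$latent, fw$latent[p, ], tolerance = 1e-10)
  expect_equal(fw_p$recon, fw$recon[p, ], tolerance = 1e-10)
})

test_that("mae loss matches hand arithmetic and is absolutely homogeneous", {
  expect_identical(mae_loss(matrix(0, 2, 2), matrix(0, 2, 2)), 0)
  X <- matrix(c(1, 3, 2, 4), 2)
  Xh <- matrix(c(2, 3, 2, 2), 2)
  expect_equal(mae_loss(X, Xh), 0.75)
  expect_equal(mae_loss(3 * X, 3 * Xh), 3 * 0.75)
  expect_error(mae_loss(X, matrix(0, 3, 2)), "shape")
})

test_that("training reduces reconstruction loss, reproducibly, for any head count", {
  sim <- small_separable_sim(n = 100, g = 150)
  X <- preprocess(sim$counts)$matrix
  E <- standardize(encode(pretrain_encoder(
    X, encoder_config(layer_dims = c(32, 16), epochs = 10, seed = 1)), X))
  g <- build_cell_graph(X, K = 3)

  for (heads in c(2, 4, 6, 8, 10)) {
    cfg <- gat_config(input_dim = ncol(E), hidden_dim = 12, latent_dim = 4,
                      n_heads = heads, epochs = 10, seed = 3)
    fit <- train_gat_autoencoder(E, g, cfg)
    expect_lte(tail(fit$state$loss_trace, 1), fit$state$loss_trace[1])
    expect_identical(dim(fit$latent), c(nrow(E), 4L))
  }

  cfg <- gat_config(input_dim = ncol(E), hidden_dim = 12, latent_dim = 4,
                    n_heads = 2, epochs = 15, seed = 7)
  f1 <- train_gat_autoencoder(E, g, cfg)
  f2 <- train_gat_autoencoder(E, g, cfg)
  expect_identical(f1$latent, f2$latent)
  expect_identical(f1$state$loss_trace, f2$state$loss_trace)
  expect_equal(gat_encode(f1$state, E, g), f1$latent)
})

test_that("analytic gradients agree with central differences", {
  n <- 10
  g <- random_graph(n, k = 3, seed = 11)
  E <- matrix(rnorm(n * 5), n)
  cfg <- gat_config(input_dim = 5, hidden_dim = 4, latent_dim = 2,
                    n_heads = 2, epochs = 0, seed = 6)
  params <- scea:::with_seed(6, scea:::gat_init_params(cfg))
  sup <- scea:::gat_support(g)
  loss <- function(p) {
    fw <- scea:::gat_ae_forward(p, E, sup, cfg)
    mean(abs(E - fw$recon))
  }
  fw <- scea:::gat_ae_forward(params, E, sup, cfg)
  grads <- scea:::gat_ae_backward(params, fw, sup, cfg,
                                  sign(fw$recon - E) / length(E))
  eps <- 1e-6
  set.seed(12)
  for (nm in sample(names(params), 6)) {
    for (k in sample(length(params[[nm]]), min(3, length(params[[nm]])))) {
      pp <- params; pp[[nm]][k] <- pp[[nm]][k] + eps
      pm <- params; pm[[nm]][k] <- pm[[nm]][k] - eps
      num <- (loss(pp) - loss(pm)) / (2 * eps)
      expect_lt(abs(num - grads[[nm]][k]), 1e-7)
    }
  }
})
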