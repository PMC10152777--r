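test_that("kmeans initialization recovers planted groupings and is deterministic", {
  set.seed(1)
  Z <- rbind(matrix(rnorm(60, 0, 0.05), 20),
             matrix(rnorm(60, 5, 0.05), 20),
             matrix(rnorm(60, -5, 0.05), 20))
  truth <- rep(1:3, each = 20)
  km <- kmeans_init(Z, 3, seed = 2)
  expect_equal(ari(truth, km$labels), 1)

  km2 <- kmeans_init(Z, 3, seed = 2)
  expect_identical(km$centers, km2$centers)

  one <- kmeans_init(Z, 1, seed = 0)
  expect_true(all(one$labels == 1L))
  expect_error(kmeans_init(Z[1:3, ], 5), "exceeds")
})

test_that("soft assignment follows the Student-t kernel", {
  # K = 1: everything belongs to the single cluster
  Q <- soft_assign(matrix(rnorm(10), 5), matrix(rnorm(2), 1))
  expect_true(all(Q == 1))

  # equidistant cell splits evenly
  Q <- soft_assign(rbind(c(0, 0)), rbind(c(1, 0), c(-1, 0)))
  expect_equal(unname(Q[1, ]), c(0.5, 0.5))

  # distance 0 vs distance 1: (1+0)^-1 vs (1+1)^-1 gives 2/3 vs 1/3
  Q <- soft_assign(rbind(c(0, 0)), rbind(c(0, 0), c(1, 0)))
  expect_equal(unname(Q[1, ]), c(2 / 3, 1 / 3))

  set.seed(3)
  Q <- soft_assign(matrix(rnorm(40), 20), matrix(rnorm(6), 3))
  expect_lt(max(abs(rowSums(Q) - 1)), 1e-8)
  expect_true(all(Q > 0))
})

test_that("target distribution sharpens and stays row-stochastic", {
  Q <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(target_distribution(Q), Q)  # symmetric fixed point

  P <- target_distribution(rbind(c(0.8, 0.2)))
  expect_equal(unname(P[1, ]), c(0.8, 0.2))  # frequencies from the single row

  set.seed(4)
  Q <- matrix(runif(60), 20); Q <- Q / rowSums(Q)
  P <- target_distribution(Q)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
  # with equal cluster frequencies, sharpening cannot raise row entropy
  Qe <- cbind(runif(30, 0.2, 0.8)); Qe <- cbind(Qe, 1 - Qe)
  Qb <- rbind(Qe, Qe[, 2:1])        # force equal frequencies by symmetry
  Pb <- target_distribution(Qb)
  h <- function(M) -rowSums(ifelse(M > 0, M * log(M), 0))
  expect_true(all(h(Pb) <= h(Qb) + 1e-12))
})

test_that("kld loss matches hand arithmetic and the Gibbs inequality", {
  P <- rbind(c(0.5, 0.5))
  expect_identical(kld_loss(P, P), 0)
  expect_equal(kld_loss(P, rbind(c(0.25, 0.75))),
               0.5 * log(2) + 0.5 * log(2 / 3), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:20) {
    A <- matrix(runif(8), 2); A <- A / rowSums(A)
    B <- matrix(runif(8), 2); B <- B / rowSums(B)
    expect_gte(kld_loss(A, B), 0)
  }
})

test_that("hard labels take the argmax with first-index tie breaking", {
  expect_identical(hard_labels(rbind(c(0.1, 0.7, 0.2))), 2L)
  expect_identical(hard_labels(rbind(c(0.5, 0.5))), 1L)
  I3 <- diag(3)[c(2, 3, 1), ]
  expect_identical(hard_labels(I3), c(2L, 3L, 1L))
})

# Shared fixture for the refinement tests: a trained small pipeline.
refine_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- small_separable_sim(n = 120, g = 200, K = 4, seed = 13)
      X <- preprocess(sim$counts)$matrix
      E <- standardize(encode(pretrain_encoder(
        X, encoder_config(layer_dims = c(32, 16), epochs = 12, seed = 1)), X))
      g <- build_cell_graph(X, K = 4)
      fit <- train_gat_autoencoder(E, g, gat_config(
        input_dim = ncol(E), hidden_dim = 16, latent_dim = 8,
        n_heads = 4, epochs = 30, seed = 2))
      km <- kmeans_init(fit$latent, 4, seed = 3)
      cache <<- list(sim = sim, E = E, g = g, fit = fit, km = km)
    }
    cache
  }
})

test_that("refinement does not destroy a good k-means solution", {
  fx <- refine_fixture()
  truth <- fx$sim$labels[match(rownames(fx$E),
                               paste0("cell_", seq_along(fx$sim$labels)))]
  ari_km <- ari(truth, fx$km$labels)
  ref <- refine(fx$fit$state, fx$E, fx$g, fx$km$centers,
                update_interval = 10, max_epochs = 40)
  expect_gte(ari(truth, ref$labels), ari_km - 0.02)
  expect_lt(max(abs(rowSums(ref$Q) - 1)), 1e-6)
  expect_true(all(is.finite(ref$trace$total)))
  expect_true(all(ref$trace$kld >= 0))
})

test_that("tolerance 1 stops refinement at the first label-change check", {
  fx <- refine_fixture()
  ref <- refine(fx$fit$state, fx$E, fx$g, fx$km$centers,
                update_interval = 5, tol = 1.0, max_epochs = 100)
  expect_identical(nrow(ref$trace), 5L)
})

test_that("pure reconstruction (lambda = 0) keeps Q row-stochastic; zero epochs equal k-means", {
  fx <- refine_fixture()
  ref <- refine(fx$fit$state, fx$E, fx$g, fx$km$centers,
                lambda_kld = 0, update_interval = 5, max_epochs = 10)
  expect_lt(max(abs(rowSums(ref$Q) - 1)), 1e-6)

  ref0 <- refine(fx$fit$state, fx$E, fx$g, fx$km$centers, max_epochs = 0)
  expect_identical(ref0$labels, fx$km$labels)
})

test_that("relabeling centers permutes Q and labels consistently", {
  fx <- refine_fixture()
  Z <- fx$fit$latent
  perm <- c(3, 1, 4, 2)
  Q1 <- soft_assign(Z, fx$km$centers)
  Q2 <- soft_assign(Z, fx$km$centers[perm, ])
  expect_equal(Q2, Q1[, perm], tolerance = 1e-12)
  l1 <- hard_labels(Q1); l2 <- hard_labels(Q2)
  expect_equal(ari(l1, l2), 1)
  expect_equal(nmi(l1, l2), 1)
})
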