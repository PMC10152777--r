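# Self-optimizing clustering head: k-means initialization of centers in
# the latent space, Student-t soft assignment, squared-sharpened target
# distribution, and joint refinement of the autoencoder and centers under
# MAE + lambda * KLD, in the deep-embedded-clustering tradition.

#' Initialize cluster centers by k-means
#'
#' Runs k-means with multiple restarts on the latent embedding and returns
#' the best-inertia solution. Deterministic given the seed.
#'
#' @param Z Cells x d latent embedding.
#' @param K Number of clusters, `K <= n_cells`.
#' @param seed Integer seed.
#' @param n_restarts Number of random restarts (default 10).
#' @return A list with `centers` (K x d), `labels` (integer 1..K) and
#'   `inertia` (total within-cluster sum of squares).
#' @export
kmeans_init <- function(Z, K, seed = 0L, n_restarts = 10) {
  Z <- as.matrix(Z)
  .check(.is_count(K) && K >= 1, "K must be a positive integer")
  .check(K <= nrow(Z), "K (", K, ") exceeds the number of cells (", nrow(Z), ")")
  if (K < 2) {
    return(list(centers = matrix(colMeans(Z), 1), labels = rep(1L, nrow(Z)),
                inertia = sum(sweep(Z, 2, colMeans(Z))^2)))
  }
  if (ncol(Z) < K)
    warning("latent width (", ncol(Z), ") is below K (", K, ")")
  with_seed(seed, {
    km <- stats::kmeans(Z, centers = K, nstart = n_restarts, iter.max = 100)
    list(centers = unname(km$centers), labels = as.integer(km$cluster),
         inertia = km$tot.withinss)
  })
}

#' Student-t soft cluster assignment
#'
#' Membership of cell i in cluster j is proportional to
#' `(1 + ||z_i - mu_j||^2)^-1` (a Student-t kernel with one degree of
#' freedom), normalized so each row sums to 1.
#'
#' @param Z Cells x d latent embedding.
#' @param centers K x d cluster centers.
#' @return Cells x K row-stochastic soft assignment matrix Q.
#' @export
soft_assign <- function(Z, centers) {
  Z <- as.matrix(Z); centers <- as.matrix(centers)
  .check(nrow(centers) >= 1, "centers must be nonempty")
  .check(ncol(Z) == ncol(centers), "Z and centers disagree on latent width")
  d2 <- outer(rowSums(Z^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(Z)), rowSums(centers^2)) - 2 * Z %*% t(centers)
  d2[d2 < 0] <- 0
  U <- 1 / (1 + d2)
  U / rowSums(U)
}

#' Target distribution for self-optimizing clustering
#'
#' Sharpens a soft assignment: `p_ij = (q_ij^2 / f_j) / sum_j'(q_ij'^2 /
#' f_j')` with cluster frequencies `f_j = sum_i q_ij`. High-confidence
#' assignments are emphasized and large clusters down-weighted.
#'
#' @param Q Row-stochastic soft assignment matrix.
#' @return Row-stochastic target matrix P of the same shape.
#' @export
target_distribution <- function(Q) {
  Q <- as.matrix(Q)
  f <- colSums(Q)
  P <- sweep(Q^2, 2, f, "/")
  P / rowSums(P)
}

#' Kullback-Leibler divergence between target and assignment
#'
#' `KL(P || Q)` summed over clusters and averaged over cells, in nats.
#' Zero entries of P contribute nothing; Q must be positive wherever P is
#' (guaranteed by the Student-t kernel).
#'
#' @param P Target distribution (rows sum to 1).
#' @param Q Soft assignment (rows sum to 1, positive support covering P).
#' @return Nonnegative scalar; 0 iff P equals Q.
#' @export
kld_loss <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  .check(identical(dim(P), dim(Q)), "P and Q must have the same shape")
  pos <- P > 0
  .check(all(Q[pos] > 0), "Q is zero where P is positive; KLD undefined")
  sum(P[pos] * log(P[pos] / Q[pos])) / nrow(P)
}

#' Hard labels from a soft assignment
#'
#' `label_i = argmax_j q_ij`, ties resolved toward the smallest index.
#'
#' @param Q Soft assignment matrix.
#' @return Integer label vector in 1..K.
#' @export
hard_labels <- function(Q) {
  Q <- as.matrix(Q)
  as.integer(max.col(Q, ties.method = "first"))
}

#' Refine clustering by joint MAE + KLD optimization
#'
#' Starting from k-means centers on the pretrained latent embedding,
#' alternates gradient steps on `mae_loss(E, recon) + lambda_kld *
#' kld_loss(P, Q)`, updating the autoencoder parameters and the cluster
#' centers jointly. The target P is recomputed every `update_interval`
#' epochs; optimization stops when the fraction of cells changing hard
#' label between consecutive target updates falls below `tol`, or at
#' `max_epochs`.
#'
#' @param state A `"gat_state"` from [train_gat_autoencoder()].
#' @param E Cells x input_dim embedding fed to the autoencoder.
#' @param graph The `"cell_graph"` used in training.
#' @param centers Initial K x latent_dim centers (from [kmeans_init()]).
#' @param lambda_kld Weight of the KLD term (default 1).
#' @param update_interval Epochs between target-distribution updates.
#' @param tol Stopping tolerance on the label-change fraction (default
#'   0.001).
#' @param max_epochs Maximum refinement epochs.
#' @param learning_rate Adam learning rate for refinement. The default
#'   (1e-4) is deliberately a tenth of the reconstruction-training rate:
#'   the KL self-training signal bootstraps from its own current
#'   assignments, and large steps can lock in early mistakes.
#' @return A list with `labels` (argmax of Q), `Q`, `centers`, `state`
#'   (refined `"gat_state"`), `latent`, and `trace` (per-epoch data frame
#'   of mae, kld and total loss).
#' @export
refine <- function(state, E, graph, centers, lambda_kld = 1,
                   update_interval = 20, tol = 0.001, max_epochs = 200,
                   learning_rate = 1e-4) {
  .check(inherits(state, "gat_state"), "state must be a gat_state")
  E <- as.matrix(E)
  centers <- as.matrix(centers)
  cfg <- state$cfg
  .check(ncol(centers) == cfg$latent_dim, "centers width must equal latent_dim")
  .check(is.numeric(lambda_kld) && lambda_kld >= 0, "lambda_kld must be >= 0")
  .check(.is_count(update_interval) && update_interval >= 1,
         "update_interval must be a positive integer")
  .check(is.numeric(tol) && tol >= 0, "tol must be >= 0")
  .check(.is_count(max_epochs) && max_epochs >= 0, "max_epochs must be >= 0")
  support <- gat_support(graph)
  n <- nrow(E)

  params <- state$params
  params$centers <- centers
  opt <- adam_init(params)

  fw <- gat_ae_forward(params[names(params) != "centers"], E, support, cfg)
  Q <- soft_assign(fw$latent, params$centers)
  P <- target_distribution(Q)
  last_labels <- hard_labels(Q)
  trace <- list()

  epoch <- 0L
  while (epoch < max_epochs) {
    epoch <- epoch + 1L
    net <- params[names(params) != "centers"]
    fw <- gat_ae_forward(net, E, support, cfg)
    Z <- fw$latent
    Q <- soft_assign(Z, params$centers)
    mae <- mean(abs(E - fw$recon))
    kld <- if (lambda_kld > 0) kld_loss(P, Q) else 0
    total <- mae + lambda_kld * kld
    if (!is.finite(total)) .fail("non-finite refinement loss at epoch ", epoch)
    trace[[epoch]] <- c(mae = mae, kld = kld, total = total)

    dRecon <- sign(fw$recon - E) / length(E)
    dLatent <- NULL
    dCenters <- matrix(0, nrow(params$centers), ncol(params$centers))
    if (lambda_kld > 0) {
      # Gradient of mean-over-cells KL(P||Q) with the Student-t kernel:
      #   dL/dz_i  =  (2/n) sum_j u_ij (p_ij - q_ij) (z_i - mu_j)
      #   dL/dmu_j = -(2/n) sum_i u_ij (p_ij - q_ij) (z_i - mu_j)
      d2 <- outer(rowSums(Z^2), rep(1, nrow(params$centers))) +
        outer(rep(1, n), rowSums(params$centers^2)) - 2 * Z %*% t(params$centers)
      d2[d2 < 0] <- 0
      U <- 1 / (1 + d2)
      C <- U * (P - Q)                        # n x K coefficients
      coef <- 2 * lambda_kld / n
      dLatent <- coef * (rowSums(C) * Z - C %*% params$centers)
      dCenters <- coef * (t(C) %*% Z - colSums(C) * params$centers)
      dCenters <- -dCenters
    }
    grads <- gat_ae_backward(net, fw, support, cfg, dRecon, dLatent)
    grads$centers <- dCenters
    st <- adam_step(params, grads, opt, learning_rate)
    params <- st$params; opt <- st$state

    if (epoch %% update_interval == 0) {
      net <- params[names(params) != "centers"]
      fw <- gat_ae_forward(net, E, support, cfg)
      Q <- soft_assign(fw$latent, params$centers)
      labels <- hard_labels(Q)
      changed <- mean(labels != last_labels)
      last_labels <- labels
      P <- target_distribution(Q)
      if (changed < tol) break
    }
  }

  net <- params[names(params) != "centers"]
  fw <- gat_ae_forward(net, E, support, cfg)
  Q <- soft_assign(fw$latent, params$centers)
  trace_df <- if (length(trace)) as.data.frame(do.call(rbind, trace)) else
    data.frame(mae = numeric(0), kld = numeric(0), total = numeric(0))
  list(labels = hard_labels(Q), Q = Q, centers = params$centers,
       state = structure(list(params = net, cfg = cfg,
                              loss_trace = state$loss_trace),
                         class = "gat_state"),
       latent = fw$latent, trace = trace_df)
}
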