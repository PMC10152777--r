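# First-stage non-linear dimension reduction: a three-layer tanh MLP
# encoder (gene space -> 4096 -> 2048 -> 1024 by default), pretrained as a
# mirrored autoencoder under mean absolute error; the decoder is discarded
# after pretraining. The final-layer tanh keeps the embedding in (-1, 1);
# an optional standardization rescales each latent dimension.

#' Configuration for the MLP encoder
#'
#' @param layer_dims Encoder layer widths, outermost first; default
#'   `c(4096, 2048, 1024)`. The embedding width is the last element.
#' @param activation Hidden/latent activation; only `"tanh"` is provided.
#' @param epochs Pretraining epochs (0 returns initialized weights).
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size; `NULL` uses full batch for up to 2048
#'   cells and 256 otherwise.
#' @param seed Integer seed for weight initialization and batch shuffling.
#' @param standardize_output Standardize the embedding after encoding
#'   (see [standardize()])?
#' @return An `"encoder_config"` object.
#' @export
encoder_config <- function(layer_dims = c(4096, 2048, 1024),
                           activation = "tanh", epochs = 30,
                           learning_rate = 1e-3, batch_size = NULL,
                           seed = 0L, standardize_output = FALSE) {
  .check(is.numeric(layer_dims) && length(layer_dims) >= 1 &&
           all(layer_dims == floor(layer_dims)) && all(layer_dims >= 1),
         "layer_dims must be positive integers")
  .check(layer_dims[length(layer_dims)] >= 2, "final layer width must be >= 2")
  if (is.unsorted(rev(layer_dims), strictly = FALSE) && length(layer_dims) > 1)
    warning("layer_dims are not decreasing; the encoder will not compress")
  .check(identical(activation, "tanh"), "only the tanh activation is supported")
  .check(.is_count(epochs) && epochs >= 0, "epochs must be a nonnegative integer")
  .check(is.numeric(learning_rate) && learning_rate > 0, "learning_rate must be positive")
  structure(list(layer_dims = as.integer(layer_dims), activation = activation,
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = batch_size, seed = as.integer(seed),
                 standardize_output = isTRUE(standardize_output)),
            class = "encoder_config")
}

mlp_init <- function(input_dim, layer_dims) {
  dims <- c(input_dim, layer_dims)
  L <- length(layer_dims)
  params <- list()
  for (l in seq_len(L)) {                      # encoder
    params[[paste0("enc_W", l)]] <- init_weight(dims[l], dims[l + 1])
    params[[paste0("enc_b", l)]] <- matrix(0, 1, dims[l + 1])
  }
  rdims <- rev(dims)
  for (l in seq_len(L)) {                      # mirrored decoder
    params[[paste0("dec_W", l)]] <- init_weight(rdims[l], rdims[l + 1])
    params[[paste0("dec_b", l)]] <- matrix(0, 1, rdims[l + 1])
  }
  params
}

# Forward pass through the full autoencoder; hidden and latent layers are
# tanh, the reconstruction layer is linear so counts-scale targets are
# reachable. Returns activations for the backward pass.
mlp_forward <- function(params, X, L) {
  acts <- vector("list", 2 * L + 1)
  acts[[1]] <- X
  A <- X
  for (l in seq_len(L)) {
    A <- act_tanh(sweep(A %*% params[[paste0("enc_W", l)]], 2,
                        params[[paste0("enc_b", l)]], "+"))
    acts[[l + 1]] <- A
  }
  for (l in seq_len(L)) {
    Z <- sweep(A %*% params[[paste0("dec_W", l)]], 2,
               params[[paste0("dec_b", l)]], "+")
    A <- if (l < L) act_tanh(Z) else Z
    acts[[L + l + 1]] <- A
  }
  acts
}

mlp_backward <- function(params, acts, L, dOut) {
  grads <- list()
  dA <- dOut
  for (l in rev(seq_len(L))) {                 # decoder
    A_out <- acts[[L + l + 1]]
    dZ <- if (l < L) dA * dact_tanh(A_out) else dA
    A_in <- acts[[L + l]]
    grads[[paste0("dec_W", l)]] <- crossprod(A_in, dZ)
    grads[[paste0("dec_b", l)]] <- matrix(colSums(dZ), 1)
    dA <- dZ %*% t(params[[paste0("dec_W", l)]])
  }
  for (l in rev(seq_len(L))) {                 # encoder
    dZ <- dA * dact_tanh(acts[[l + 1]])
    grads[[paste0("enc_W", l)]] <- crossprod(acts[[l]], dZ)
    grads[[paste0("enc_b", l)]] <- matrix(colSums(dZ), 1)
    dA <- dZ %*% t(params[[paste0("enc_W", l)]])
  }
  grads
}

#' Pretrain the MLP encoder as a mirrored autoencoder
#'
#' Trains encoder + mirrored decoder to minimize the mean absolute error
#' between the (preprocessed) input matrix and its reconstruction, using
#' Adam. The decoder exists only for pretraining; [encode()] uses the
#' encoder half.
#'
#' @param X Preprocessed (filtered, normalized) cells x genes matrix.
#' @param cfg An [encoder_config()].
#' @return An `"encoder_state"` with trained `params`, the `cfg`,
#'   `input_dim`, and `loss_trace` (per-epoch mean MAE; empty for 0 epochs).
#' @export
pretrain_encoder <- function(X, cfg = encoder_config()) {
  .check(inherits(cfg, "encoder_config"), "cfg must be an encoder_config")
  X <- as.matrix(X)
  .check(nrow(X) >= 1 && ncol(X) >= 1, "empty input matrix")
  .check(all(is.finite(X)), "input contains non-finite values")
  if (ncol(X) < cfg$layer_dims[1])
    warning("input gene count (", ncol(X), ") is below the first layer width (",
            cfg$layer_dims[1], "); the first layer expands rather than compresses")
  L <- length(cfg$layer_dims)
  n <- nrow(X)
  batch <- cfg$batch_size
  if (is.null(batch)) batch <- if (n <= 2048) n else 256L

  with_seed(cfg$seed, {
    params <- mlp_init(ncol(X), cfg$layer_dims)
    opt <- adam_init(params)
    trace <- numeric(0)
    if (cfg$epochs > 0) {
      for (epoch in seq_len(cfg$epochs)) {
        idx <- if (batch >= n) list(seq_len(n)) else
          split(sample.int(n), ceiling(seq_len(n) / batch))
        losses <- numeric(0)
        for (b in idx) {
          Xb <- X[b, , drop = FALSE]
          acts <- mlp_forward(params, Xb, L)
          recon <- acts[[2 * L + 1]]
          loss <- mean(abs(Xb - recon))
          if (!is.finite(loss))
            .fail("non-finite pretraining loss at epoch ", epoch)
          dOut <- sign(recon - Xb) / length(Xb)
          grads <- mlp_backward(params, acts, L, dOut)
          st <- adam_step(params, grads, opt, cfg$learning_rate)
          params <- st$params; opt <- st$state
          losses <- c(losses, loss)
        }
        trace <- c(trace, mean(losses))
      }
    }
    structure(list(params = params, cfg = cfg, input_dim = ncol(X),
                   input_genes = colnames(X), loss_trace = trace),
              class = "encoder_state")
  })
}

#' Encode cells into the latent space
#'
#' Applies the trained encoder half. With tanh activations every output
#' entry lies in (-1, 1); standardization (if requested in the config) is a
#' separate, explicit step via [standardize()].
#'
#' @param state An `"encoder_state"` from [pretrain_encoder()].
#' @param X Matrix whose column count equals the trained input width.
#' @return Cells x d embedding matrix (d = last layer width).
#' @export
encode <- function(state, X) {
  .check(inherits(state, "encoder_state"), "state must be an encoder_state")
  X <- as.matrix(X)
  .check(ncol(X) == state$input_dim,
         "input width ", ncol(X), " does not match trained width ", state$input_dim)
  L <- length(state$cfg$layer_dims)
  A <- X
  for (l in seq_len(L)) {
    A <- act_tanh(sweep(A %*% state$params[[paste0("enc_W", l)]], 2,
                        state$params[[paste0("enc_b", l)]], "+"))
  }
  rownames(A) <- rownames(X)
  A
}

#' Standardize an embedding per latent dimension
#'
#' Subtracts the column mean and divides by the population standard
#' deviation (ddof = 0). Constant columns (sd = 0) become all-zero.
#'
#' @param E Cells x d embedding matrix.
#' @return Standardized matrix of the same shape.
#' @export
standardize <- function(E) {
  E <- as.matrix(E)
  mu <- colMeans(E)
  sd_pop <- sqrt(colMeans(sweep(E, 2, mu)^2))
  out <- sweep(E, 2, mu)
  nz <- sd_pop > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, sd_pop[nz], "/")
  out[, !nz] <- 0
  out
}

#' Save / load an encoder state
#'
#' Writes the weights as an RDS file with a JSON sidecar holding the
#' configuration and loss trace.
#'
#' @param state An `"encoder_state"`.
#' @param path Weights file path; the sidecar is `<path>.json`.
#' @return `save_encoder` the path, invisibly; `load_encoder` the state.
#' @export
save_encoder <- function(state, path) {
  .check(inherits(state, "encoder_state"), "state must be an encoder_state")
  saveRDS(state, path)
  jsonlite::write_json(list(cfg = unclass(state$cfg), input_dim = state$input_dim,
                            loss_trace = state$loss_trace),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_encoder
#' @export
load_encoder <- function(path) {
  state <- readRDS(path)
  .check(inherits(state, "encoder_state"), "file does not contain an encoder_state")
  state
}
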