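# Second-stage dimension reduction: a multi-head graph attention
# autoencoder. Encoder = two attention layers (input -> hidden -> latent),
# decoder = structurally symmetric (latent -> hidden -> input) with its own
# parameters. Per head, edge scores are
#   e_ij = LeakyReLU(a_src . W h_i + a_dst . W h_j)
# restricted to the graph support plus mandatory self-loops, softmaxed over
# each node's neighborhood, and used to aggregate neighbor features.
# Heads are concatenated on hidden layers (ELU activation) and averaged on
# the latent/reconstruction layers (linear). Trained with MAE + Adam.
# Attention is computed densely with a -Inf mask off support, so logits
# outside the graph can never influence the output; n stays modest (cells),
# so dense n x n per head is the simplest correct choice.

#' Configuration for the graph attention autoencoder
#'
#' @param input_dim Width of the input embedding (MLP output; 1024 default).
#' @param hidden_dim Merged hidden width; rounded up to a multiple of
#'   `n_heads` (per-head width = `ceiling(hidden_dim / n_heads)`).
#' @param latent_dim Latent width; should comfortably exceed the expected
#'   cluster count (a warning is issued otherwise at clustering time).
#' @param n_heads Number of attention heads (default 8).
#' @param leaky_slope Negative slope of the LeakyReLU scoring nonlinearity.
#' @param epochs Training epochs.
#' @param learning_rate Adam learning rate.
#' @param seed Integer seed.
#' @return A `"gat_config"` object.
#' @export
gat_config <- function(input_dim = 1024, hidden_dim = 256, latent_dim = 64,
                       n_heads = 8, leaky_slope = 0.2, epochs = 100,
                       learning_rate = 1e-3, seed = 0L) {
  .check(.is_count(input_dim) && input_dim >= 1, "input_dim must be a positive integer")
  .check(.is_count(hidden_dim) && hidden_dim >= 1, "hidden_dim must be a positive integer")
  .check(.is_count(latent_dim) && latent_dim >= 2, "latent_dim must be an integer >= 2")
  .check(.is_count(n_heads) && n_heads >= 1, "n_heads must be a positive integer")
  .check(is.numeric(leaky_slope) && leaky_slope >= 0, "leaky_slope must be >= 0")
  .check(.is_count(epochs) && epochs >= 0, "epochs must be a nonnegative integer")
  .check(is.numeric(learning_rate) && learning_rate > 0, "learning_rate must be positive")
  structure(list(input_dim = as.integer(input_dim), hidden_dim = as.integer(hidden_dim),
                 latent_dim = as.integer(latent_dim), n_heads = as.integer(n_heads),
                 leaky_slope = leaky_slope, epochs = as.integer(epochs),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "gat_config")
}

# Support mask: graph edges plus mandatory self-loops, so every node
# attends at least to itself.
gat_support <- function(graph) {
  .check(inherits(graph, "cell_graph"), "graph must be a cell_graph")
  S <- graph$adjacency != 0
  diag(S) <- TRUE
  S
}

# Layer geometry for the 4-layer autoencoder given a config.
gat_layout <- function(cfg) {
  per_head <- as.integer(ceiling(cfg$hidden_dim / cfg$n_heads))
  hidden_eff <- per_head * cfg$n_heads
  list(
    list(name = "enc1", in_dim = cfg$input_dim, out_dim = per_head,
         merge = "concat", act = "elu"),
    list(name = "enc2", in_dim = hidden_eff, out_dim = cfg$latent_dim,
         merge = "average", act = "identity"),
    list(name = "dec1", in_dim = cfg$latent_dim, out_dim = per_head,
         merge = "concat", act = "elu"),
    list(name = "dec2", in_dim = hidden_eff, out_dim = cfg$input_dim,
         merge = "average", act = "identity"))
}

#' Initialize parameters for one attention layer
#'
#' @param input_dim,out_dim Per-head input and output widths.
#' @param n_heads Number of heads.
#' @param seed Integer seed.
#' @return Named list with, per head `h`: `h<h>_W` (input_dim x out_dim),
#'   `h<h>_a_src`, `h<h>_a_dst` (out_dim x 1 scoring vectors).
#' @export
gat_layer_params <- function(input_dim, out_dim, n_heads, seed = 0L) {
  with_seed(seed, {
    params <- list()
    for (h in seq_len(n_heads)) {
      params[[paste0("h", h, "_W")]] <- init_weight(input_dim, out_dim)
      params[[paste0("h", h, "_a_src")]] <- init_weight(out_dim, 1)
      params[[paste0("h", h, "_a_dst")]] <- init_weight(out_dim, 1)
    }
    params
  })
}

# Forward pass of one multi-head attention layer (dense masked softmax).
# Returns merged activated output, per-head attention maps, and the cache
# needed for the backward pass.
gat_layer_forward <- function(params, H, support, n_heads, merge, act, slope) {
  n <- nrow(H)
  heads <- vector("list", n_heads)
  outs <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    W <- params[[paste0("h", h, "_W")]]
    M <- H %*% W
    f <- drop(M %*% params[[paste0("h", h, "_a_src")]])
    g <- drop(M %*% params[[paste0("h", h, "_a_dst")]])
    Epre <- matrix(f, n, n) + matrix(g, n, n, byrow = TRUE)
    Elr <- act_lrelu(Epre, slope)
    logits <- ifelse(support, Elr, -Inf)
    mx <- apply(logits, 1, max)
    A <- exp(logits - mx)
    A[!support] <- 0
    A <- A / rowSums(A)
    O <- A %*% M
    heads[[h]] <- list(M = M, A = A, Epre = Epre)
    outs[[h]] <- O
  }
  pre <- if (merge == "concat") do.call(cbind, outs) else Reduce(`+`, outs) / n_heads
  out <- if (act == "elu") act_elu(pre) else pre
  list(out = out, heads = heads, H = H, merge = merge, act = act,
       n_heads = n_heads, out_dim = ncol(outs[[1]]))
}

# Backward pass of one attention layer. dOut is the gradient at the merged,
# activated output; returns parameter gradients and the gradient dH at the
# layer input.
gat_layer_backward <- function(params, cache, support, slope, dOut) {
  n <- nrow(cache$H)
  n_heads <- cache$n_heads
  d <- cache$out_dim
  dPre <- if (cache$act == "elu") dOut * dact_elu(cache$out) else dOut
  grads <- list()
  dH <- matrix(0, n, nrow(params[["h1_W"]]))
  for (h in seq_len(n_heads)) {
    c_h <- cache$heads[[h]]
    dO <- if (cache$merge == "concat") {
      dPre[, ((h - 1) * d + 1):(h * d), drop = FALSE]
    } else {
      dPre / n_heads
    }
    M <- c_h$M; A <- c_h$A
    dA <- (dO %*% t(M))
    dA[!support] <- 0
    dM <- crossprod(A, dO)
    # softmax backward on each row's support
    dE <- A * (dA - rowSums(dA * A))
    dEpre <- dE * dact_lrelu(c_h$Epre, slope)
    df <- rowSums(dEpre)
    dg <- colSums(dEpre)
    a_src <- params[[paste0("h", h, "_a_src")]]
    a_dst <- params[[paste0("h", h, "_a_dst")]]
    dM <- dM + df %o% drop(a_src) + dg %o% drop(a_dst)
    grads[[paste0("h", h, "_a_src")]] <- crossprod(M, matrix(df, ncol = 1))
    grads[[paste0("h", h, "_a_dst")]] <- crossprod(M, matrix(dg, ncol = 1))
    W <- params[[paste0("h", h, "_W")]]
    grads[[paste0("h", h, "_W")]] <- crossprod(cache$H, dM)
    dH <- dH + dM %*% t(W)
  }
  list(grads = grads, dH = dH)
}

#' Apply one multi-head graph attention layer
#'
#' User-facing single-layer application, e.g. for inspecting attention
#' maps. Self-loops are always added to the graph support. Each head's
#' attention map is row-stochastic on the support.
#'
#' @param H Node feature matrix (cells x features).
#' @param graph A `"cell_graph"`; only the edge support is used.
#' @param params Layer parameters from [gat_layer_params()]; freshly
#'   initialized from `seed` when `NULL`.
#' @param n_heads Number of heads.
#' @param merge `"concat"` or `"average"`.
#' @param out_dim Per-head output width (required when `params` is `NULL`).
#' @param activation `"elu"` or `"identity"`.
#' @param leaky_slope LeakyReLU negative slope for edge scores.
#' @param seed Seed for initialization when `params` is `NULL`.
#' @return A list with `out` (merged node features) and `attention` (list of
#'   per-head n x n row-stochastic matrices supported on edges + self-loops).
#' @export
attention_layer <- function(H, graph, params = NULL, n_heads = 8,
                            merge = c("concat", "average"), out_dim = NULL,
                            activation = c("elu", "identity"),
                            leaky_slope = 0.2, seed = 0L) {
  merge <- match.arg(merge)
  activation <- match.arg(activation)
  H <- as.matrix(H)
  support <- gat_support(graph)
  .check(nrow(H) == nrow(support),
         "feature row count (", nrow(H), ") does not match graph size (",
         nrow(support), ")")
  if (is.null(params)) {
    .check(!is.null(out_dim), "out_dim is required when params is NULL")
    params <- gat_layer_params(ncol(H), out_dim, n_heads, seed)
  }
  fw <- gat_layer_forward(params, H, support, n_heads, merge, activation, leaky_slope)
  list(out = fw$out, attention = lapply(fw$heads, `[[`, "A"))
}

gat_init_params <- function(cfg) {
  layout <- gat_layout(cfg)
  params <- list()
  for (layer in layout) {
    for (h in seq_len(cfg$n_heads)) {
      params[[paste0(layer$name, "_h", h, "_W")]] <- init_weight(layer$in_dim, layer$out_dim)
      params[[paste0(layer$name, "_h", h, "_a_src")]] <- init_weight(layer$out_dim, 1)
      params[[paste0(layer$name, "_h", h, "_a_dst")]] <- init_weight(layer$out_dim, 1)
    }
  }
  params
}

# Slice the flat parameter list of the full model down to one layer,
# renaming to the per-layer "h<h>_*" convention.
gat_slice <- function(params, layer_name, n_heads) {
  out <- list()
  for (h in seq_len(n_heads)) {
    for (p in c("W", "a_src", "a_dst")) {
      out[[paste0("h", h, "_", p)]] <- params[[paste0(layer_name, "_h", h, "_", p)]]
    }
  }
  out
}

gat_ae_forward <- function(params, E, support, cfg) {
  layout <- gat_layout(cfg)
  caches <- vector("list", 4)
  A <- E
  for (i in seq_along(layout)) {
    lay <- layout[[i]]
    caches[[i]] <- gat_layer_forward(gat_slice(params, lay$name, cfg$n_heads),
                                     A, support, cfg$n_heads, lay$merge,
                                     lay$act, cfg$leaky_slope)
    A <- caches[[i]]$out
  }
  list(latent = caches[[2]]$out, recon = caches[[4]]$out, caches = caches)
}

# Backward through the full autoencoder. dRecon is the loss gradient at the
# reconstruction; dLatentExtra (may be NULL) is an additional gradient
# injected at the latent layer (used by the clustering refinement).
gat_ae_backward <- function(params, fw, support, cfg, dRecon, dLatentExtra = NULL) {
  layout <- gat_layout(cfg)
  grads <- list()
  dA <- dRecon
  for (i in c(4, 3)) {
    lay <- layout[[i]]
    bw <- gat_layer_backward(gat_slice(params, lay$name, cfg$n_heads),
                             fw$caches[[i]], support, cfg$leaky_slope, dA)
    for (nm in names(bw$grads))
      grads[[paste0(lay$name, "_", nm)]] <- bw$grads[[nm]]
    dA <- bw$dH
  }
  if (!is.null(dLatentExtra)) dA <- dA + dLatentExtra
  for (i in c(2, 1)) {
    lay <- layout[[i]]
    bw <- gat_layer_backward(gat_slice(params, lay$name, cfg$n_heads),
                             fw$caches[[i]], support, cfg$leaky_slope, dA)
    for (nm in names(bw$grads))
      grads[[paste0(lay$name, "_", nm)]] <- bw$grads[[nm]]
    dA <- bw$dH
  }
  grads
}

#' Train the graph attention autoencoder
#'
#' Full-batch Adam training of the two-layer attention encoder and its
#' structurally symmetric decoder under mean absolute reconstruction error
#' over the cell graph.
#'
#' @param E Cells x input_dim embedding (MLP output, optionally
#'   standardized).
#' @param graph A `"cell_graph"` over the same cells.
#' @param cfg A [gat_config()]; `cfg$input_dim` must equal `ncol(E)`.
#' @return A list with `state` (a `"gat_state"`: trained `params`, `cfg`,
#'   `loss_trace`) and `latent` (cells x latent_dim embedding).
#' @export
train_gat_autoencoder <- function(E, graph, cfg = NULL) {
  E <- as.matrix(E)
  if (is.null(cfg)) cfg <- gat_config(input_dim = ncol(E))
  .check(inherits(cfg, "gat_config"), "cfg must be a gat_config")
  .check(cfg$input_dim == ncol(E),
         "cfg$input_dim (", cfg$input_dim, ") does not match ncol(E) (", ncol(E), ")")
  support <- gat_support(graph)
  .check(nrow(E) == nrow(support), "embedding and graph disagree on cell count")

  with_seed(cfg$seed, {
    params <- gat_init_params(cfg)
    opt <- adam_init(params)
    trace <- numeric(0)
    for (epoch in seq_len(cfg$epochs)) {
      fw <- gat_ae_forward(params, E, support, cfg)
      loss <- mean(abs(E - fw$recon))
      if (!is.finite(loss)) .fail("non-finite GAT loss at epoch ", epoch)
      dRecon <- sign(fw$recon - E) / length(E)
      grads <- gat_ae_backward(params, fw, support, cfg, dRecon)
      st <- adam_step(params, grads, opt, cfg$learning_rate)
      params <- st$params; opt <- st$state
      trace <- c(trace, loss)
    }
    fw <- gat_ae_forward(params, E, support, cfg)
    latent <- fw$latent
    rownames(latent) <- rownames(E)
    list(state = structure(list(params = params, cfg = cfg, loss_trace = trace),
                           class = "gat_state"),
         latent = latent)
  })
}

#' Encode with a trained graph attention autoencoder
#'
#' @param state A `"gat_state"` from [train_gat_autoencoder()].
#' @param E Cells x input_dim embedding.
#' @param graph The `"cell_graph"` used in training (or one over the same
#'   cells).
#' @return Cells x latent_dim latent embedding.
#' @export
gat_encode <- function(state, E, graph) {
  .check(inherits(state, "gat_state"), "state must be a gat_state")
  E <- as.matrix(E)
  support <- gat_support(graph)
  fw <- gat_ae_forward(state$params, E, support, state$cfg)
  latent <- fw$latent
  rownames(latent) <- rownames(E)
  latent
}
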