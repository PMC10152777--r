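# Shared neural-network primitives: seeded weight initialization and an
# Adam optimizer over named lists of parameter matrices. All gradients in
# the package are hand-derived reverse-mode; no external framework is used.

# Uniform fan-in initialization: U(-1/sqrt(fan_in), 1/sqrt(fan_in)).
init_weight <- function(fan_in, fan_out) {
  lim <- 1 / sqrt(fan_in)
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

adam_init <- function(params) {
  zeros <- lapply(params, function(p) p * 0)
  list(t = 0L, m = zeros, v = zeros)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Activations and their derivatives expressed via the forward output.
act_tanh <- function(z) tanh(z)
dact_tanh <- function(a) 1 - a * a
act_elu <- function(z) ifelse(z > 0, z, expm1(z))
dact_elu <- function(a) ifelse(a > 0, 1, a + 1)
act_lrelu <- function(z, slope) ifelse(z > 0, z, slope * z)
dact_lrelu <- function(z, slope) ifelse(z > 0, 1, slope)

#' Mean absolute error between two matrices
#'
#' The reconstruction loss used by both autoencoder stages: the mean over
#' all entries of `|X - X_hat|`.
#'
#' @param X,X_hat Matrices of identical shape.
#' @return A nonnegative scalar.
#' @export
mae_loss <- function(X, X_hat) {
  .check(identical(dim(X), dim(X_hat)),
         "shape mismatch: ", paste(dim(X), collapse = "x"), " vs ",
         paste(dim(X_hat), collapse = "x"))
  mean(abs(X - X_hat))
}
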