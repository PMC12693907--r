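# Shared numerical machinery for the package's neural models: seeded uniform
# fan-in initialization, activations, row-wise softmax, and an Adam optimizer
# operating on flat named lists of numeric arrays.

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Row-wise softmax with max-shift for numerical stability.
softmax_rows <- function(s) {
  s <- s - apply(s, 1L, max)
  e <- exp(s)
  e / rowSums(e)
}

# Uniform(-1/sqrt(fan_in), 1/sqrt(fan_in)) weight matrix (n_out x n_in).
# Draws from the current RNG stream; callers seed via withr::with_seed.
init_weight <- function(n_out, n_in) {
  lim <- 1 / sqrt(n_in)
  matrix(runif(n_out * n_in, -lim, lim), n_out, n_in)
}

init_bias <- function(n_out) numeric(n_out)

# Adam state for a flat named list of numeric arrays.
adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

# One Adam update. `params` and `grads` are parallel flat named lists.
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Zero-filled gradient accumulator mirroring a parameter list.
zero_like <- function(params) {
  lapply(params, function(p) {
    if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
  })
}

# Minibatch index blocks after a seeded shuffle (RNG from current stream).
minibatches <- function(n, batch_size) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

# Slice time step t out of an (S, T, X) window array as an S x X matrix.
window_slice <- function(w, t) {
  matrix(w[, t, ], nrow = dim(w)[1], ncol = dim(w)[3])
}

# Per-epoch learning rate: constant, or geometric decay to config$lr_final.
epoch_lr <- function(config, ep, epochs) {
  if (is.null(config$lr_final) || epochs <= 1) return(config$lr)
  config$lr * (config$lr_final / config$lr)^((ep - 1) / (epochs - 1))
}
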