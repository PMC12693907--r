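# Independent scalar/loop oracles used to cross-check the package's batched
# implementations. Deliberately written with explicit element-wise sums, not
# matrix algebra.

osigmoid <- function(x) 1 / (1 + exp(-x))

omatvec <- function(W, v) {
  out <- numeric(nrow(W))
  for (i in seq_len(nrow(W))) {
    acc <- 0
    for (j in seq_len(ncol(W))) acc <- acc + W[i, j] * v[j]
    out[i] <- acc
  }
  out
}

# LSTM cell step by explicit loops over the gate equations.
oracle_lstm_step <- function(x, h, c_prev, p) {
  z <- c(h, x)
  f <- osigmoid(omatvec(p$W_f, z) + p$b_f)
  u <- osigmoid(omatvec(p$W_u, z) + p$b_u)
  cc <- tanh(omatvec(p$W_c, z) + p$b_c)
  c_new <- f * c_prev + u * cc
  o <- osigmoid(omatvec(p$W_o, z) + p$b_o)
  list(h = o * tanh(c_new), c = c_new)
}

# GRU cell step by explicit loops.
oracle_gru_step <- function(x, h, p) {
  r <- osigmoid(omatvec(p$w_xr, x) + omatvec(p$w_hr, h) + p$b_r)
  z <- osigmoid(omatvec(p$w_xz, x) + omatvec(p$w_hz, h) + p$b_z)
  hc <- tanh(omatvec(p$w_xh, x) + omatvec(p$w_hh, r * h) + p$b_h)
  z * h + (1 - z) * hc
}

# Attention by explicit summation: query from the last state.
oracle_attention <- function(H, p) {
  T_steps <- nrow(H)
  q <- omatvec(p$W_Q, H[T_steps, ])
  scores <- numeric(T_steps)
  for (t in seq_len(T_steps)) {
    k <- omatvec(p$W_K, H[t, ])
    scores[t] <- sum(k * q)
  }
  e <- exp(scores - max(scores))
  alpha <- e / sum(e)
  ctx <- numeric(length(q))
  for (t in seq_len(T_steps)) {
    ctx <- ctx + alpha[t] * omatvec(p$W_V, H[t, ])
  }
  list(weights = alpha, context = ctx)
}

# Feed-forward network by explicit loop-and-sum.
oracle_dnn <- function(x, p) {
  h <- x
  for (l in 1:3) {
    h <- pmax(omatvec(p[[paste0("w", l)]], h) + p[[paste0("b", l)]], 0)
  }
  omatvec(p$w4, h) + p$b4
}

# Type-7 quantile by hand: sorted-order linear interpolation.
oracle_quantile <- function(v, prob) {
  v <- sort(v)
  pos <- (length(v) - 1) * prob + 1
  lo <- floor(pos)
  hi <- ceiling(pos)
  v[lo] + (pos - lo) * (v[hi] - v[lo])
}

# Brute-force point-in-polygon (ray casting, with explicit boundary check).
oracle_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  on_edge <- function(x, y) {
    for (i in seq_len(n)) {
      j <- if (i == n) 1 else i + 1
      cross <- (vx[j] - vx[i]) * (y - vy[i]) - (vy[j] - vy[i]) * (x - vx[i])
      if (abs(cross) < 1e-9 &&
          x >= min(vx[i], vx[j]) - 1e-9 && x <= max(vx[i], vx[j]) + 1e-9 &&
          y >= min(vy[i], vy[j]) - 1e-9 && y <= max(vy[i], vy[j]) + 1e-9) {
        return(TRUE)
      }
    }
    FALSE
  }
  if (on_edge(px, py)) return(TRUE)
  crossings <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    if ((vy[i] > py) != (vy[j] > py)) {
      xint <- vx[i] + (py - vy[i]) / (vy[j] - vy[i]) * (vx[j] - vx[i])
      if (px < xint) crossings <- crossings + 1
    }
  }
  crossings %% 2 == 1
}

# Uniform image with the given channel means.
flat_image <- function(r, g, b, h = 8, w = 8) {
  img <- array(0, c(h, w, 3))
  img[, , 1] <- r; img[, , 2] <- g; img[, , 3] <- b
  img
}

# Noiseless training pairs from the simulator's trait response curves.
toy_quality_data <- function(n = 60, seed = 53) {
  a <- withr::with_seed(seed, runif(n, 0.4, 0.68))
  traits <- purrr::map_dfc(
    c("FI", "SSC", "SS", "TA", "VC", "LYC"),
    function(tr) tibble::tibble("{tr}" := quality_response(a, tr)))
  list(a = a, traits = traits)
}
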