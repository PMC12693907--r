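# GRU encoder with query-key-value attention for predicting tomato surface
# color fractions (red, yellow, green) from joint environment + color history.
#
# GRU cell:
#   r_t = sigmoid(w_xr x_t + w_hr h_{t-1} + b_r)       (reset gate)
#   z_t = sigmoid(w_xz x_t + w_hz h_{t-1} + b_z)       (update gate)
#   h~_t = tanh(w_xh x_t + w_hh (r_t * h_{t-1}) + b_h) (candidate)
#   h_t = z_t * h_{t-1} + (1 - z_t) * h~_t
#
# Attention over all hidden states, query from the final state:
#   q = W_Q h_T,  K_t = W_K h_t,  V_t = W_V h_t
#   alpha = softmax_t(K_t . q),  context = sum_t alpha_t V_t
#
# Head: y = W_o ReLU(W_FC context + b_FC) + b_o  (3 outputs), post-processed
# onto the 3-simplex at prediction time.

#' GRU cell parameters
#'
#' @param input_size,hidden_size Input and hidden dimensions.
#' @return List with `w_xr`, `w_hr`, `w_xz`, `w_hz`, `w_xh`, `w_hh` and
#'   biases `b_r`, `b_z`, `b_h`.
#' @export
gru_cell_params <- function(input_size, hidden_size) {
  list(w_xr = init_weight(hidden_size, input_size),
       w_hr = init_weight(hidden_size, hidden_size),
       w_xz = init_weight(hidden_size, input_size),
       w_hz = init_weight(hidden_size, hidden_size),
       w_xh = init_weight(hidden_size, input_size),
       w_hh = init_weight(hidden_size, hidden_size),
       b_r = init_bias(hidden_size), b_z = init_bias(hidden_size),
       b_h = init_bias(hidden_size),
       hidden_size = hidden_size, input_size = input_size)
}

#' One GRU cell step
#'
#' @param x Input vector.
#' @param h_prev Previous hidden state.
#' @param params [gru_cell_params()].
#' @return New hidden state vector.
#' @export
gru_cell_step <- function(x, h_prev, params) {
  if (length(x) != ncol(params$w_xr) || length(h_prev) != ncol(params$w_hr)) {
    abort("input/state size inconsistent with cell parameters.")
  }
  r <- sigmoid(drop(params$w_xr %*% x) + drop(params$w_hr %*% h_prev) + params$b_r)
  z <- sigmoid(drop(params$w_xz %*% x) + drop(params$w_hz %*% h_prev) + params$b_z)
  h_cand <- tanh(drop(params$w_xh %*% x) +
                 drop(params$w_hh %*% (r * h_prev)) + params$b_h)
  z * h_prev + (1 - z) * h_cand
}

#' Attention parameter matrices
#'
#' @param hidden_size Hidden state dimension.
#' @param dim Shared projection (inner) dimension.
#' @return List with `W_Q`, `W_K`, `W_V` (`dim x hidden_size`).
#' @export
attention_params <- function(hidden_size, dim) {
  list(W_Q = init_weight(dim, hidden_size),
       W_K = init_weight(dim, hidden_size),
       W_V = init_weight(dim, hidden_size))
}

#' Query-key-value attention over a hidden-state sequence
#'
#' Projects each hidden state to a key and value and the final state to the
#' query, scores keys against the query by dot product, normalizes with
#' softmax, and returns the weighted sum of values.
#'
#' @param H `T x hidden` matrix of hidden states (rows = time steps).
#' @param params [attention_params()].
#' @return List with `weights` (length T, nonnegative, summing to 1) and
#'   `context` (length `dim`).
#' @export
attention <- function(H, params) {
  if (is.null(dim(H)) || nrow(H) < 1) {
    abort("attention needs at least one hidden state.")
  }
  q <- drop(params$W_Q %*% H[nrow(H), ])
  K <- H %*% t(params$W_K)   # T x dim
  V <- H %*% t(params$W_V)   # T x dim
  scores <- drop(K %*% q)
  alpha <- drop(softmax_rows(matrix(scores, 1)))
  list(weights = alpha, context = drop(t(V) %*% alpha))
}

#' Ripeness model configuration
#'
#' Six input features (temperature, humidity, radiation, red, yellow, green
#' fractions), window length 24; Adam with learning rate 0.001, batch size
#' 64, 150 epochs. The GRU hidden size and attention/FC widths are exposed
#' (single GRU layer, hidden 64 by default).
#'
#' @param hidden GRU hidden units.
#' @param att_dim Attention projection dimension.
#' @param fc Fully connected layer width.
#' @param T_steps,x_dim Window shape (defaults 24 x 6).
#' @param lr,batch_size,epochs Optimizer settings.
#' @param input_noise SD of Gaussian jitter added to training windows; as
#'   predictions are fed back recursively over multi-day rollouts, jitter
#'   training keeps the one-step map from compounding its own errors.
#' @param lr_final If set, the learning rate decays geometrically from `lr`
#'   to `lr_final` over the epochs (see [env_config()]).
#' @param seed RNG seed.
#' @return A `maturity_config` list.
#' @export
maturity_config <- function(hidden = 64, att_dim = 32, fc = 32, T_steps = 24,
                            x_dim = 6, lr = 0.001, batch_size = 64,
                            epochs = 150, input_noise = 0.02,
                            lr_final = NULL, seed = 42L) {
  if (hidden < 1 || att_dim < 1 || fc < 1) {
    abort("sizes must be positive.", class = "ripecast_config_error")
  }
  structure(list(hidden = as.integer(hidden), att_dim = as.integer(att_dim),
                 fc = as.integer(fc), T_steps = T_steps, x_dim = x_dim,
                 lr = lr, batch_size = batch_size, epochs = epochs,
                 input_noise = input_noise, lr_final = lr_final,
                 seed = as.integer(seed)),
            class = "maturity_config")
}

#' Build a GRU-attention ripeness model
#'
#' @param config A [maturity_config()].
#' @return A `gruat_model` object predicting (red, yellow, green) fractions.
#' @export
build_maturity_model <- function(config) {
  params <- withr::with_seed(config$seed, {
    gru <- gru_cell_params(config$x_dim, config$hidden)
    att <- attention_params(config$hidden, config$att_dim)
    list(w_xr = gru$w_xr, w_hr = gru$w_hr, w_xz = gru$w_xz, w_hz = gru$w_hz,
         w_xh = gru$w_xh, w_hh = gru$w_hh,
         b_r = gru$b_r, b_z = gru$b_z, b_h = gru$b_h,
         W_Q = att$W_Q, W_K = att$W_K, W_V = att$W_V,
         fc_W = init_weight(config$fc, config$att_dim),
         fc_b = init_bias(config$fc),
         out_W = init_weight(3, config$fc), out_b = init_bias(3))
  })
  structure(list(config = config, params = params,
                 history = tibble::tibble(epoch = integer(), loss = numeric())),
            class = c("gruat_model", "ripecast_model"))
}

# Batched forward over (S, T, 6) windows. Returns raw 3-column outputs and
# caches for backprop when `keep`.
gruat_forward_batch <- function(params, config, windows, keep = FALSE) {
  s <- dim(windows)[1]; T_steps <- dim(windows)[2]; H <- config$hidden
  Wx <- cbind(t(params$w_xr), t(params$w_xz))   # X x 2H
  Wh <- cbind(t(params$w_hr), t(params$w_hz))   # H x 2H
  h <- matrix(0, s, H)
  hs <- vector("list", T_steps)
  cache <- if (keep) vector("list", T_steps)
  for (t in seq_len(T_steps)) {
    x <- window_slice(windows, t)
    a_rz <- x %*% Wx + h %*% Wh
    a_rz <- sweep(a_rz, 2, c(params$b_r, params$b_z), "+")
    r <- sigmoid(a_rz[, 1:H, drop = FALSE])
    z <- sigmoid(a_rz[, (H + 1):(2 * H), drop = FALSE])
    rh <- r * h
    hc <- tanh(sweep(x %*% t(params$w_xh) + rh %*% t(params$w_hh), 2,
                     params$b_h, "+"))
    h_prev <- h
    h <- z * h_prev + (1 - z) * hc
    if (keep) cache[[t]] <- list(x = x, r = r, z = z, rh = rh, hc = hc,
                                 h_prev = h_prev)
    hs[[t]] <- h
  }
  # attention: query from final state
  q <- h %*% t(params$W_Q)                       # S x d
  Ks <- lapply(hs, function(ht) ht %*% t(params$W_K))
  Vs <- lapply(hs, function(ht) ht %*% t(params$W_V))
  scores <- vapply(Ks, function(K) rowSums(K * q), numeric(s))
  scores <- matrix(scores, s, T_steps)
  alpha <- softmax_rows(scores)
  context <- matrix(0, s, config$att_dim)
  for (t in seq_len(T_steps)) context <- context + alpha[, t] * Vs[[t]]
  fc_pre <- sweep(context %*% t(params$fc_W), 2, params$fc_b, "+")
  fc <- relu(fc_pre)
  y <- sweep(fc %*% t(params$out_W), 2, params$out_b, "+")
  list(y = y, alpha = alpha,
       cache = if (keep) list(gru = cache, hs = hs, q = q, Ks = Ks, Vs = Vs,
                              alpha = alpha, context = context,
                              fc_pre = fc_pre, fc = fc))
}

gruat_backward_batch <- function(params, config, fw, d_y) {
  cc <- fw$cache
  s <- nrow(d_y); H <- config$hidden
  T_steps <- length(cc$gru)
  grads <- zero_like(params)
  # head
  d_fc <- tcrossprod(d_y, t(params$out_W))        # S x fc
  grads$out_W <- crossprod(d_y, cc$fc)
  grads$out_b <- colSums(d_y)
  d_fc_pre <- d_fc * (cc$fc_pre > 0)
  grads$fc_W <- crossprod(d_fc_pre, cc$context)
  grads$fc_b <- colSums(d_fc_pre)
  d_context <- d_fc_pre %*% params$fc_W           # S x d
  # attention
  d_alpha <- matrix(0, s, T_steps)
  d_hs <- lapply(seq_len(T_steps), function(t) matrix(0, s, H))
  for (t in seq_len(T_steps)) {
    dV <- cc$alpha[, t] * d_context
    grads$W_V <- grads$W_V + crossprod(dV, cc$hs[[t]])
    d_hs[[t]] <- d_hs[[t]] + dV %*% params$W_V
    d_alpha[, t] <- rowSums(d_context * cc$Vs[[t]])
  }
  d_scores <- cc$alpha * (d_alpha - rowSums(d_alpha * cc$alpha))
  d_q <- matrix(0, s, config$att_dim)
  for (t in seq_len(T_steps)) {
    d_q <- d_q + d_scores[, t] * cc$Ks[[t]]
    dK <- d_scores[, t] * cc$q
    grads$W_K <- grads$W_K + crossprod(dK, cc$hs[[t]])
    d_hs[[t]] <- d_hs[[t]] + dK %*% params$W_K
  }
  grads$W_Q <- crossprod(d_q, cc$hs[[T_steps]])
  d_hs[[T_steps]] <- d_hs[[T_steps]] + d_q %*% params$W_Q
  # GRU backward through time
  dh <- matrix(0, s, H)
  for (t in seq(T_steps, 1)) {
    ch <- cc$gru[[t]]
    dh_tot <- dh + d_hs[[t]]
    dz <- dh_tot * (ch$h_prev - ch$hc)
    dhc <- dh_tot * (1 - ch$z)
    dh <- dh_tot * ch$z
    da_h <- dhc * (1 - ch$hc^2)
    grads$w_xh <- grads$w_xh + crossprod(da_h, ch$x)
    grads$w_hh <- grads$w_hh + crossprod(da_h, ch$rh)
    grads$b_h <- grads$b_h + colSums(da_h)
    d_rh <- da_h %*% params$w_hh
    dr <- d_rh * ch$h_prev
    dh <- dh + d_rh * ch$r
    da_r <- dr * ch$r * (1 - ch$r)
    da_z <- dz * ch$z * (1 - ch$z)
    grads$w_xr <- grads$w_xr + crossprod(da_r, ch$x)
    grads$w_hr <- grads$w_hr + crossprod(da_r, ch$h_prev)
    grads$b_r <- grads$b_r + colSums(da_r)
    grads$w_xz <- grads$w_xz + crossprod(da_z, ch$x)
    grads$w_hz <- grads$w_hz + crossprod(da_z, ch$h_prev)
    grads$b_z <- grads$b_z + colSums(da_z)
    dh <- dh + da_r %*% params$w_hr + da_z %*% params$w_hz
  }
  grads
}

# Project raw 3-vector rows onto the simplex: clip to [0,1], renormalize.
simplex_project <- function(y) {
  y <- pmin(pmax(y, 0), 1)
  s <- rowSums(y)
  zero <- s <= 0
  y[zero, ] <- 1 / 3
  s[zero] <- 1
  y / s
}

#' Forward pass of the ripeness model
#'
#' Runs the GRU over a `T x 6` window, attends over all hidden states, and
#' maps the context through the ReLU fully connected layer and linear head.
#' Outputs are clipped to \[0, 1\] and renormalized to sum to 1 (surface
#' fractions live on the 3-simplex).
#'
#' @param model A `gruat_model`.
#' @param window `T x 6` matrix of scaled features (or an `(S, T, 6)` array).
#' @return Tibble with `red`, `yellow`, `green` columns.
#' @export
gruat_forward <- function(model, window) {
  config <- model$config
  if (is.matrix(window)) window <- array(window, c(1, nrow(window), ncol(window)))
  d <- dim(window)
  if (length(d) != 3 || d[2] != config$T_steps || d[3] != config$x_dim) {
    abort(sprintf("window must be %d x %d.", config$T_steps, config$x_dim))
  }
  y <- simplex_project(gruat_forward_batch(model$params, config, window)$y)
  tibble::tibble(red = y[, 1], yellow = y[, 2], green = y[, 3])
}

#' Train the ripeness model
#'
#' Minimizes MSE over the three fraction outputs (equal weights) with Adam
#' over seeded minibatches. Windows pair environment channels (observed
#' during training, forecaster rollouts at inference) with lagged color
#' fractions; targets are next-step fractions.
#'
#' @param model A [build_maturity_model()] result.
#' @param data List with `windows` (`S x T x 6`) and `targets` (`S x 3`).
#' @param epochs Override `config$epochs`.
#' @param verbose Print loss every 25 epochs.
#' @return Trained model with `$history`.
#' @export
train_maturity <- function(model, data, epochs = NULL, verbose = FALSE) {
  config <- model$config
  epochs <- epochs %||% config$epochs
  if (epochs == 0) return(model)
  params <- model$params
  opt <- adam_init(params)
  n <- dim(data$windows)[1]
  y <- as.matrix(data$targets)[, 1:3]
  history <- numeric(epochs)
  withr::with_seed(config$seed + 1L, {
    for (ep in seq_len(epochs)) {
      lr_ep <- epoch_lr(config, ep, epochs)
      ep_loss <- 0
      for (idx in minibatches(n, config$batch_size)) {
        w <- data$windows[idx, , , drop = FALSE]
        if (isTRUE(config$input_noise > 0)) {
          w <- w + rnorm(length(w), 0, config$input_noise)
        }
        fw <- gruat_forward_batch(params, config, w, keep = TRUE)
        err <- fw$y - y[idx, , drop = FALSE]
        loss <- mean(err^2)
        if (!is.finite(loss)) {
          abort(sprintf("training diverged (non-finite loss) at epoch %d.", ep),
                class = "ripecast_divergence")
        }
        grads <- gruat_backward_batch(params, config, fw,
                                      2 * err / length(err))
        upd <- adam_step(params, grads, opt, lr_ep)
        params <- upd$params; opt <- upd$state
        ep_loss <- ep_loss + loss * length(idx)
      }
      history[ep] <- ep_loss / n
      if (verbose && ep %% 25 == 0) {
        message(sprintf("[gruat] epoch %d loss %.6f", ep, history[ep]))
      }
    }
  })
  model$params <- params
  model$history <- dplyr::bind_rows(
    model$history,
    tibble::tibble(epoch = seq_len(epochs) + nrow(model$history),
                   loss = history))
  model
}

#' Predict color fractions for a batch of windows
#'
#' @param model Trained `gruat_model`.
#' @param windows `(S, T, 6)` array (or a single `T x 6` matrix).
#' @return Tibble with simplex-projected `red`, `yellow`, `green`.
#' @export
predict_maturity <- function(model, windows) {
  gruat_forward(model, windows)
}
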