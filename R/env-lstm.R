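# Stacked-LSTM next-step forecaster for greenhouse temperature, humidity and
# radiation. The cell follows the classic gate equations
#   f_t = sigmoid(W_f [H_{t-1}, X_t] + b_f)      (forget gate)
#   u_t = sigmoid(W_u [H_{t-1}, X_t] + b_u)      (update gate)
#   c~_t = tanh(W_c [H_{t-1}, X_t] + b_c)        (candidate cell state)
#   C_t = f_t * C_{t-1} + u_t * c~_t
#   o_t = sigmoid(W_o [H_{t-1}, X_t] + b_o)      (output gate)
#   H_t = o_t * tanh(C_t)
# Training is full backpropagation through time with Adam, batched over
# samples so each time step is a single BLAS matrix product.

#' LSTM cell parameters
#'
#' Weight matrices act on the concatenation `[H_{t-1}, X_t]` (hidden part
#' first). Initialization is uniform in +/- 1/sqrt(fan-in) from the current
#' RNG stream.
#'
#' @param input_size,hidden_size Input and hidden dimensions.
#' @return List with `W_f`, `W_u`, `W_c`, `W_o` (hidden x (hidden+input))
#'   and biases `b_f`, `b_u`, `b_c`, `b_o`.
#' @export
lstm_cell_params <- function(input_size, hidden_size) {
  d <- hidden_size + input_size
  list(W_f = init_weight(hidden_size, d), b_f = init_bias(hidden_size),
       W_u = init_weight(hidden_size, d), b_u = init_bias(hidden_size),
       W_c = init_weight(hidden_size, d), b_c = init_bias(hidden_size),
       W_o = init_weight(hidden_size, d), b_o = init_bias(hidden_size),
       hidden_size = hidden_size, input_size = input_size)
}

#' One LSTM cell step
#'
#' Applies the gate equations to a single input vector and state.
#'
#' @param x Input vector.
#' @param state List with `h` (hidden state) and `c` (cell state).
#' @param params [lstm_cell_params()].
#' @return Updated state list with `h` and `c`.
#' @export
lstm_cell_step <- function(x, state, params) {
  z <- c(state$h, x)
  if (length(z) != ncol(params$W_f)) {
    abort("state/input size inconsistent with cell parameters.")
  }
  f <- sigmoid(drop(params$W_f %*% z) + params$b_f)
  u <- sigmoid(drop(params$W_u %*% z) + params$b_u)
  cc <- tanh(drop(params$W_c %*% z) + params$b_c)
  c_new <- f * state$c + u * cc
  o <- sigmoid(drop(params$W_o %*% z) + params$b_o)
  list(h = o * tanh(c_new), c = c_new)
}

# Pack named cell params into the column-blocked [f|u|c|o] layout used by the
# batched passes: W is (hidden+input) x 4*hidden, b length 4*hidden.
pack_lstm_layer <- function(cell) {
  list(W = t(rbind(cell$W_f, cell$W_u, cell$W_c, cell$W_o)),
       b = c(cell$b_f, cell$b_u, cell$b_c, cell$b_o))
}

#' Environment model configuration
#'
#' Per-variable stacked-LSTM architectures: temperature 3 layers x 100
#' units, humidity 1 x 160, radiation 2 x 64; window length `T = 24`; Adam
#' with learning rate 0.001, batch size 32, 150 epochs, MSE loss.
#'
#' @param variable `"temperature"`, `"humidity"`, or `"radiation"`.
#' @param layers,hidden Override the per-variable architecture.
#' @param T_steps,x_dim Window length and feature count.
#' @param lr,batch_size,epochs Optimizer settings.
#' @param input_noise SD of Gaussian jitter added to training windows
#'   (scaled units). Because forecasts are fed back recursively at rollout,
#'   training on jittered inputs teaches the one-step map to contract back
#'   toward the clean trajectory instead of compounding its own errors.
#' @param lr_final If set, the learning rate decays geometrically from `lr`
#'   to `lr_final` over the epochs; annealing settles the one-step map much
#'   closer to its minimum, which multi-step rollouts amplify.
#' @param seed Seed for initialization and batch shuffling.
#' @return An `env_config` list.
#' @export
env_config <- function(variable, layers = NULL, hidden = NULL, T_steps = 24,
                       x_dim = 3, lr = 0.001, batch_size = 32, epochs = 150,
                       input_noise = 0.02, lr_final = NULL, seed = 42L) {
  arch <- switch(variable,
                 temperature = list(layers = 3L, hidden = 100L),
                 humidity    = list(layers = 1L, hidden = 160L),
                 radiation   = list(layers = 2L, hidden = 64L),
                 abort(sprintf("unknown variable '%s'.", variable),
                       class = "ripecast_config_error"))
  layers <- layers %||% arch$layers
  hidden <- hidden %||% arch$hidden
  if (layers < 1 || hidden < 1) {
    abort("layers and hidden units must be positive.",
          class = "ripecast_config_error")
  }
  structure(list(variable = variable, layers = as.integer(layers),
                 hidden = as.integer(hidden), T_steps = T_steps,
                 x_dim = x_dim, lr = lr, batch_size = batch_size,
                 epochs = epochs, input_noise = input_noise,
                 lr_final = lr_final, seed = as.integer(seed)),
            class = "env_config")
}

#' Build a stacked-LSTM forecaster
#'
#' Stacks `config$layers` LSTM layers (the first consuming all `x_dim`
#' features, deeper layers consuming the hidden sequence below) and maps the
#' final hidden state through a fully connected layer to one scalar — the
#' next-step value of the configured variable in scaled units.
#'
#' @param config An [env_config()].
#' @return An `env_lstm` model object.
#' @export
build_env_model <- function(config) {
  params <- withr::with_seed(config$seed, {
    p <- list()
    in_size <- config$x_dim
    for (l in seq_len(config$layers)) {
      p[[paste0("l", l)]] <- pack_lstm_layer(
        lstm_cell_params(in_size, config$hidden))
      in_size <- config$hidden
    }
    p$head_W <- init_weight(1, config$hidden)
    p$head_b <- init_bias(1)
    p
  })
  structure(list(config = config, params = flatten_lstm(params),
                 history = tibble::tibble(epoch = integer(), loss = numeric()),
                 scaler = NULL),
            class = c("env_lstm", "ripecast_model"))
}

flatten_lstm <- function(p) {
  out <- list()
  for (nm in names(p)) {
    if (grepl("^l\\d+$", nm)) {
      out[[paste0(nm, ".W")]] <- p[[nm]]$W
      out[[paste0(nm, ".b")]] <- p[[nm]]$b
    } else out[[nm]] <- p[[nm]]
  }
  out
}

# Batched forward over an (S, T, X) window array. Returns predictions and,
# if `keep`, the caches needed for backpropagation.
lstm_forward_batch <- function(params, config, windows, keep = FALSE) {
  s <- dim(windows)[1]; T_steps <- dim(windows)[2]
  H <- config$hidden; L <- config$layers
  caches <- if (keep) vector("list", L)
  inputs <- lapply(seq_len(T_steps), function(t) window_slice(windows, t))
  for (l in seq_len(L)) {
    W <- params[[paste0("l", l, ".W")]]
    b <- params[[paste0("l", l, ".b")]]
    h <- matrix(0, s, H); cs <- matrix(0, s, H)
    cache <- if (keep) vector("list", T_steps)
    outputs <- vector("list", T_steps)
    for (t in seq_len(T_steps)) {
      z <- cbind(h, inputs[[t]])
      a <- z %*% W
      a <- sweep(a, 2, b, "+")
      f <- sigmoid(a[, 1:H, drop = FALSE])
      u <- sigmoid(a[, (H + 1):(2 * H), drop = FALSE])
      cc <- tanh(a[, (2 * H + 1):(3 * H), drop = FALSE])
      o <- sigmoid(a[, (3 * H + 1):(4 * H), drop = FALSE])
      c_prev <- cs
      cs <- f * c_prev + u * cc
      tc <- tanh(cs)
      h <- o * tc
      if (keep) cache[[t]] <- list(z = z, f = f, u = u, cc = cc, o = o,
                                   c_prev = c_prev, tc = tc)
      outputs[[t]] <- h
    }
    if (keep) caches[[l]] <- cache
    inputs <- outputs
  }
  h_final <- inputs[[T_steps]]
  pred <- drop(h_final %*% t(params$head_W)) + params$head_b
  list(pred = pred, h_final = h_final, caches = caches,
       top_outputs = if (keep) inputs)
}

# Backward pass matching lstm_forward_batch. d_pred: gradient of loss wrt
# predictions (length S). Returns flat gradient list.
lstm_backward_batch <- function(params, config, fw, d_pred) {
  s <- length(d_pred); H <- config$hidden; L <- config$layers
  T_steps <- length(fw$caches[[1]])
  grads <- zero_like(params)
  grads$head_W <- matrix(d_pred, 1, s) %*% fw$h_final
  grads$head_b <- sum(d_pred)
  # gradient arriving at each layer's hidden outputs, per time step
  d_out <- vector("list", T_steps)
  for (t in seq_len(T_steps)) d_out[[t]] <- matrix(0, s, H)
  d_out[[T_steps]] <- d_pred * matrix(params$head_W, s, H, byrow = TRUE)
  for (l in seq(L, 1)) {
    W <- params[[paste0("l", l, ".W")]]
    cache <- fw$caches[[l]]
    in_size <- ncol(cache[[1]]$z) - H
    dW <- matrix(0, nrow(W), ncol(W)); db <- numeric(length(params[[paste0("l", l, ".b")]]))
    d_below <- if (l > 1) {
      lapply(seq_len(T_steps), function(t) matrix(0, s, H))
    }
    dh <- matrix(0, s, H); dc <- matrix(0, s, H)
    for (t in seq(T_steps, 1)) {
      ch <- cache[[t]]
      dh_tot <- dh + d_out[[t]]
      do_ <- dh_tot * ch$tc
      dc <- dc + dh_tot * ch$o * (1 - ch$tc^2)
      df <- dc * ch$c_prev
      du <- dc * ch$cc
      dcc <- dc * ch$u
      dA <- cbind(df * ch$f * (1 - ch$f),
                  du * ch$u * (1 - ch$u),
                  dcc * (1 - ch$cc^2),
                  do_ * ch$o * (1 - ch$o))
      dW <- dW + crossprod(ch$z, dA)
      db <- db + colSums(dA)
      dZ <- tcrossprod(dA, W)
      dh <- dZ[, 1:H, drop = FALSE]
      if (l > 1) d_below[[t]] <- dZ[, (H + 1):(H + in_size), drop = FALSE]
      dc <- dc * ch$f
    }
    grads[[paste0("l", l, ".W")]] <- dW
    grads[[paste0("l", l, ".b")]] <- db
    if (l > 1) d_out <- d_below
  }
  grads
}

#' Train an environment forecaster
#'
#' Minimizes next-step MSE with Adam over seeded minibatches. All inputs are
#' expected min-max scaled to \[0, 1\].
#'
#' @param model An [build_env_model()] result.
#' @param data A [windowize()] dataset whose `vars` include the model's
#'   target variable.
#' @param epochs Override `config$epochs` (0 returns the model unchanged).
#' @param scaler Optional [minmax_scaler()] stored for later inverse
#'   transforms.
#' @param verbose Print the loss every 25 epochs.
#' @return The trained model; `$history` holds per-epoch training loss.
#' @export
train_env <- function(model, data, epochs = NULL, scaler = NULL,
                      verbose = FALSE) {
  config <- model$config
  epochs <- epochs %||% config$epochs
  if (!is.null(scaler)) model$scaler <- scaler
  if (epochs == 0) return(model)
  target_col <- match(config$variable, data$vars)
  if (is.na(target_col)) abort("target variable not in dataset.")
  y <- data$targets[, target_col]
  params <- model$params
  opt <- adam_init(params)
  n <- dim(data$windows)[1]
  history <- numeric(epochs)
  withr::with_seed(config$seed + 1L, {
    for (ep in seq_len(epochs)) {
      lr_ep <- epoch_lr(config, ep, epochs)
      ep_loss <- 0
      batches <- minibatches(n, config$batch_size)
      for (idx in batches) {
        w <- data$windows[idx, , , drop = FALSE]
        if (isTRUE(config$input_noise > 0)) {
          # element-wise jitter plus a per-window, per-channel offset: the
          # offset mimics the correlated level error a recursive rollout
          # feeds back, so the map learns to contract toward the attractor
          d <- dim(w)
          offs <- array(rep(rnorm(d[1] * d[3], 0, config$input_noise),
                            each = 1), c(d[1], 1, d[3]))
          w <- w + rnorm(length(w), 0, config$input_noise) +
            array(offs[, rep(1, d[2]), ], d)
          fw <- lstm_forward_batch(params, config, w, keep = TRUE)
        } else {
          fw <- lstm_forward_batch(params, config, w, keep = TRUE)
        }
        err <- fw$pred - y[idx]
        loss <- mean(err^2)
        if (!is.finite(loss)) {
          abort(sprintf("training diverged (non-finite loss) at epoch %d.", ep),
                class = "ripecast_divergence")
        }
        grads <- lstm_backward_batch(params, config, fw, 2 * err / length(idx))
        upd <- adam_step(params, grads, opt, lr_ep)
        params <- upd$params; opt <- upd$state
        ep_loss <- ep_loss + loss * length(idx)
      }
      history[ep] <- ep_loss / n
      if (verbose && ep %% 25 == 0) {
        message(sprintf("[%s] epoch %d loss %.6f", config$variable, ep,
                        history[ep]))
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

#' Next-step prediction from a window
#'
#' @param model Trained `env_lstm`.
#' @param window `T x X` matrix of scaled inputs (or an `(S, T, X)` array
#'   for a batch).
#' @return Numeric vector of next-step predictions in scaled units.
#' @export
predict_env <- function(model, window) {
  config <- model$config
  if (is.matrix(window)) {
    window <- array(window, c(1, nrow(window), ncol(window)))
  }
  d <- dim(window)
  if (length(d) != 3 || d[2] != config$T_steps || d[3] != config$x_dim) {
    abort(sprintf("window must be %d x %d (T x X).", config$T_steps,
                  config$x_dim))
  }
  if (max(abs(window)) > 10) {
    warn("window values look unscaled (|x| >> 1); expected min-max scaled inputs.")
  }
  lstm_forward_batch(model$params, config, window)$pred
}

#' Recursive multi-step environment rollout
#'
#' Rolls the three per-variable forecasters forward `horizon` steps, feeding
#' each step's predictions back into the shared window.
#'
#' @param models Named list of trained `env_lstm` models, one per variable
#'   in the window's column order.
#' @param window `T x X` matrix of scaled history, columns ordered like
#'   `names(models)`.
#' @param horizon Number of steps to roll out.
#' @return Tibble with `step` and one scaled column per variable.
#' @export
forecast_env <- function(models, window, horizon) {
  if (horizon < 1) abort("horizon must be >= 1.",
                         class = "ripecast_config_error")
  vars <- names(models)
  out <- matrix(NA_real_, horizon, length(vars),
                dimnames = list(NULL, vars))
  for (s in seq_len(horizon)) {
    nxt <- vapply(vars, function(v) predict_env(models[[v]], window),
                  numeric(1))
    out[s, ] <- nxt
    window <- rbind(window[-1, , drop = FALSE], nxt)
  }
  dplyr::bind_cols(tibble::tibble(step = seq_len(horizon)),
                   tibble::as_tibble(out))
}
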