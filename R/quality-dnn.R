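# Multi-task feed-forward regression from the normalized CIELAB a* feature
# to six quality traits: FI (kg/cm2), SSC (degrees Brix), SS (mg/g), TA (%),
# VC (mg/g), LYC (mg/g).
#
#   H1 = ReLU(w1 X + b1)   (256 units)
#   H2 = ReLU(w2 H1 + b2)  (128 units)
#   H3 = ReLU(w3 H2 + b3)  (64 units)
#   Y  = w4 H3 + b4        (6 outputs, standardized per trait)
#
# Dropout (rate 0.4, inverted scaling) after each hidden layer during
# training only. The multi-task loss is sum_k lambda_k MSE_k with weights
# adapted each epoch toward harder tasks and renormalized to sum 6.

QUALITY_TRAITS <- c("FI", "SSC", "SS", "TA", "VC", "LYC")

#' DNN parameters
#'
#' @param sizes Layer widths, input through output
#'   (default `c(1, 256, 128, 64, 6)`).
#' @return List of weight matrices `w1`..`w4` and biases `b1`..`b4`.
#' @export
dnn_params <- function(sizes = c(1, 256, 128, 64, 6)) {
  stopifnot(length(sizes) == 5)
  p <- list()
  for (l in 1:4) {
    p[[paste0("w", l)]] <- init_weight(sizes[l + 1], sizes[l])
    p[[paste0("b", l)]] <- init_bias(sizes[l + 1])
  }
  p
}

#' DNN forward pass
#'
#' @param x Numeric vector of inputs (one scalar feature per sample), or an
#'   `S x d_in` matrix.
#' @param params [dnn_params()].
#' @param dropout Dropout rate applied after each hidden layer; only active
#'   when `training = TRUE` (inverted dropout, masks drawn from the current
#'   RNG stream).
#' @param training Logical.
#' @return `S x 6` matrix of standardized-scale outputs (plus a `"cache"`
#'   attribute when `training = TRUE`).
#' @export
dnn_forward <- function(x, params, dropout = 0, training = FALSE) {
  x <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  hs <- list(x)
  masks <- list()
  pre <- list()
  h <- x
  for (l in 1:3) {
    a <- sweep(h %*% t(params[[paste0("w", l)]]), 2, params[[paste0("b", l)]], "+")
    h <- relu(a)
    if (training && dropout > 0) {
      m <- matrix(stats::rbinom(length(h), 1, 1 - dropout), nrow(h)) / (1 - dropout)
      h <- h * m
      masks[[l]] <- m
    }
    pre[[l]] <- a
    hs[[l + 1]] <- h
  }
  y <- sweep(h %*% t(params$w4), 2, params$b4, "+")
  if (training) {
    attr(y, "cache") <- list(hs = hs, pre = pre, masks = masks)
  }
  y
}

dnn_backward <- function(params, cache, d_y, dropout) {
  grads <- zero_like(params)
  grads$w4 <- crossprod(d_y, cache$hs[[4]])
  grads$b4 <- colSums(d_y)
  dh <- d_y %*% params$w4
  for (l in 3:1) {
    if (length(cache$masks) >= l && !is.null(cache$masks[[l]])) {
      dh <- dh * cache$masks[[l]]
    }
    da <- dh * (cache$pre[[l]] > 0)
    grads[[paste0("w", l)]] <- crossprod(da, cache$hs[[l]])
    grads[[paste0("b", l)]] <- colSums(da)
    if (l > 1) dh <- da %*% params[[paste0("w", l)]]
  }
  grads
}

#' Adaptively weighted multi-task loss
#'
#' `loss = sum_k lambda_k MSE_k` over the six standardized traits. After
#' each epoch the weights are refreshed as
#' `lambda_k = 6 * m_k^gamma / sum_j m_j^gamma` from (a moving average of)
#' the per-task errors `m_k`, so harder tasks are upweighted; weights stay
#' positive and always sum to 6.
#'
#' @param predictions,targets `S x 6` matrices on the standardized scale.
#' @param weights Length-6 positive weights summing to 6.
#' @return List with `loss`, `per_task_mse`, and `weights` (unchanged here;
#'   use [update_task_weights()] between epochs).
#' @export
adaptive_multitask_loss <- function(predictions, targets, weights = rep(1, 6)) {
  err <- predictions - targets
  per_task <- colMeans(err^2)
  if (any(!is.finite(per_task))) {
    abort("non-finite task error.", class = "ripecast_divergence")
  }
  list(loss = sum(weights * per_task), per_task_mse = per_task,
       weights = weights)
}

#' @rdname adaptive_multitask_loss
#' @param task_mse Length-6 recent per-task MSEs (moving average).
#' @param gamma Exponent tempering the upweighting (default 0.5).
#' @export
update_task_weights <- function(task_mse, gamma = 0.5) {
  if (all(task_mse == 0)) return(rep(1, 6))
  w <- task_mse^gamma
  6 * w / sum(w)
}

#' Quality model configuration
#'
#' Adam with learning rate 0.001, batch size 16, 100 epochs; dropout 0.4
#' between hidden layers; adaptive-weight exponent `gamma = 0.5` with an
#' exponential moving average of per-task errors.
#'
#' @param sizes Layer widths.
#' @param lr,batch_size,epochs Optimizer settings.
#' @param dropout Hidden-layer dropout rate during training.
#' @param gamma Adaptive-weight exponent.
#' @param ema Smoothing factor for the per-task error average.
#' @param seed RNG seed.
#' @return A `quality_config` list.
#' @export
quality_config <- function(sizes = c(1, 256, 128, 64, 6), lr = 0.001,
                           batch_size = 16, epochs = 100, dropout = 0.4,
                           gamma = 0.5, ema = 0.7, seed = 42L) {
  structure(list(sizes = sizes, lr = lr, batch_size = batch_size,
                 epochs = epochs, dropout = dropout, gamma = gamma,
                 ema = ema, seed = as.integer(seed)),
            class = "quality_config")
}

#' Build the quality DNN
#'
#' @param config A [quality_config()].
#' @return A `quality_dnn` model.
#' @export
build_quality_model <- function(config = quality_config()) {
  params <- withr::with_seed(config$seed, dnn_params(config$sizes))
  structure(list(config = config, params = params, scalers = NULL,
                 weights = rep(1, 6),
                 history = tibble::tibble(epoch = integer(), loss = numeric())),
            class = c("quality_dnn", "ripecast_model"))
}

# Per-trait standardization fitted on training targets.
fit_task_scalers <- function(targets) {
  tibble::tibble(
    trait = colnames(targets),
    mean = colMeans(targets),
    sd = apply(targets, 2, function(v) {
      s <- stats::sd(v)
      if (!is.finite(s) || s == 0) 1 else s
    })
  )
}

standardize_targets <- function(targets, scalers) {
  sweep(sweep(targets, 2, scalers$mean, "-"), 2, scalers$sd, "/")
}

destandardize_targets <- function(y, scalers) {
  sweep(sweep(y, 2, scalers$sd, "*"), 2, scalers$mean, "+")
}

#' Train the quality DNN
#'
#' Standardizes each trait independently on the training targets, then
#' minimizes the adaptively weighted multi-task loss with Adam over seeded
#' minibatches.
#'
#' @param model A [build_quality_model()] result.
#' @param a_norm Numeric vector of normalized a* inputs in \[0, 1\].
#' @param traits Data frame with columns `FI`, `SSC`, `SS`, `TA`, `VC`,
#'   `LYC`.
#' @param epochs Override `config$epochs`.
#' @param verbose Print loss every 25 epochs.
#' @return Trained model; `$history` has per-epoch weighted loss, and
#'   `$weights` the final task weights.
#' @export
train_quality <- function(model, a_norm, traits, epochs = NULL,
                          verbose = FALSE) {
  config <- model$config
  epochs <- epochs %||% config$epochs
  targets <- as.matrix(tibble::as_tibble(traits)[, QUALITY_TRAITS])
  model$scalers <- model$scalers %||% fit_task_scalers(targets)
  if (epochs == 0) return(model)
  y <- standardize_targets(targets, model$scalers)
  params <- model$params
  weights <- model$weights
  opt <- adam_init(params)
  n <- length(a_norm)
  history <- numeric(epochs)
  mse_ema <- NULL
  withr::with_seed(config$seed + 1L, {
    for (ep in seq_len(epochs)) {
      ep_tasks <- numeric(6)
      ep_loss <- 0
      for (idx in minibatches(n, config$batch_size)) {
        pred <- dnn_forward(a_norm[idx], params, dropout = config$dropout,
                            training = TRUE)
        cache <- attr(pred, "cache")
        ml <- adaptive_multitask_loss(unclass(pred)[, , drop = FALSE],
                                      y[idx, , drop = FALSE], weights)
        # d/dpred of sum_k lambda_k mean_i(err_ik^2)
        d_y <- sweep(2 * (pred - y[idx, , drop = FALSE]) / length(idx),
                     2, weights, "*")
        grads <- dnn_backward(params, cache, d_y, config$dropout)
        upd <- adam_step(params, grads, opt, config$lr)
        params <- upd$params; opt <- upd$state
        ep_tasks <- ep_tasks + ml$per_task_mse * length(idx)
        ep_loss <- ep_loss + ml$loss * length(idx)
      }
      ep_tasks <- ep_tasks / n
      mse_ema <- if (is.null(mse_ema)) ep_tasks else
        config$ema * mse_ema + (1 - config$ema) * ep_tasks
      weights <- update_task_weights(mse_ema, config$gamma)
      history[ep] <- ep_loss / n
      if (verbose && ep %% 25 == 0) {
        message(sprintf("[quality] epoch %d loss %.6f", ep, history[ep]))
      }
    }
  })
  model$params <- params
  model$weights <- weights
  model$history <- dplyr::bind_rows(
    model$history,
    tibble::tibble(epoch = seq_len(epochs) + nrow(model$history),
                   loss = history))
  model
}

#' Predict quality traits from normalized a*
#'
#' De-standardizes the network outputs and clamps them at zero from below
#' (the traits are physical quantities).
#'
#' @param model Trained `quality_dnn`.
#' @param a_norm Numeric vector in \[0, 1\] (out-of-range values trigger a
#'   warning but are not clamped).
#' @return Tibble with one row per input and columns `FI`, `SSC`, `SS`,
#'   `TA`, `VC`, `LYC`.
#' @export
predict_quality <- function(model, a_norm) {
  if (any(a_norm < 0 | a_norm > 1)) {
    warn("a_norm values outside [0, 1]; the model was trained on normalized inputs.")
  }
  y <- dnn_forward(a_norm, model$params)
  y <- destandardize_targets(y, model$scalers)
  y <- pmax(y, 0)
  colnames(y) <- QUALITY_TRAITS
  tibble::as_tibble(y)
}
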