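# Pipeline orchestration: preprocessing sensors end to end, assembling the
# ripeness dataset, calibrating the red-fraction -> a_norm proxy, running the
# integrated environment -> color -> quality prediction, and portable JSON
# checkpoints.

ENV_VARS <- c("temperature", "humidity", "radiation")

#' Preprocess a sensor series
#'
#' Runs the full quality-control chain: box-plot outlier flagging, two-branch
#' gap filling, and min-max scaling (scaler fitted here or supplied, e.g.
#' fitted on the training split).
#'
#' @param data Sensor tibble (`timestamp` + variables).
#' @param scaler Optional pre-fitted [minmax_scaler()].
#' @param max_linear_gap Passed to [fill_gaps()].
#' @return List with `scaled` (tibble in \[0, 1\]), `filled` (physical
#'   units, gaps filled), and `scaler`.
#' @export
preprocess_sensors <- function(data, scaler = NULL, max_linear_gap = 5) {
  qc <- qc_outliers(data)
  filled <- fill_gaps(qc, max_linear_gap = max_linear_gap)
  scaler <- scaler %||% minmax_scaler(filled)
  list(scaled = scale_minmax(filled, scaler), filled = filled,
       scaler = scaler)
}

#' Assemble the ripeness (GRU-AT) dataset
#'
#' Joins scaled environment channels with per-plant color fractions on
#' timestamp and windows the six feature channels within each plant, with
#' next-step fractions as targets.
#'
#' @param env_scaled Scaled environment tibble.
#' @param colors Per-plant color tibble (`plant_id`, `timestamp`, `red`,
#'   `yellow`, `green`).
#' @param T_steps Window length (default 24).
#' @return A [windowize_by_plant()] dataset with X = 6.
#' @export
assemble_maturity_dataset <- function(env_scaled, colors, T_steps = 24) {
  joined <- dplyr::inner_join(colors, env_scaled, by = "timestamp")
  joined <- dplyr::arrange(joined, .data$plant_id, .data$timestamp)
  windowize_by_plant(joined, T_steps,
                     vars = c(ENV_VARS, "red", "yellow", "green"),
                     target_vars = c("red", "yellow", "green"))
}

#' Calibrate the red-fraction to a* proxy
#'
#' The integrated rollout has no future image from which to extract a*, so
#' the scalar DNN input is obtained from the predicted red fraction through
#' a monotone map calibrated on training data: an isotonic regression of
#' observed `a_norm` on observed red fraction, linearly interpolated.
#'
#' @param red Observed red fractions (training split).
#' @param a_norm Matching observed normalized a* values.
#' @return A function mapping red fractions to a_norm.
#' @export
fit_anorm_proxy <- function(red, a_norm) {
  iso <- isoreg(red, a_norm)
  ord <- iso$ord %||% seq_along(iso$x) # yf is in sorted-x order
  fx <- approxfun(iso$x[ord], iso$yf, rule = 2, ties = mean)
  structure(fx, class = c("anorm_proxy", "function"))
}

#' Integrated environment -> color -> quality prediction
#'
#' Rolls the three environment forecasters forward recursively, feeds each
#' predicted step (with the lagged color fractions) to the ripeness model,
#' grades maturity, converts the predicted red fraction to a_norm through
#' the calibrated proxy, and predicts the six quality traits.
#'
#' @param env_models Named list of trained `env_lstm` models
#'   (`temperature`, `humidity`, `radiation`).
#' @param maturity_model Trained `gruat_model`.
#' @param quality_model Trained `quality_dnn`.
#' @param anorm_proxy A [fit_anorm_proxy()] function.
#' @param window `T x 6` matrix of scaled history (environment channels then
#'   red, yellow, green).
#' @param horizon Steps to roll forward (>= 1).
#' @return Tibble with one row per step: predicted environment (scaled),
#'   fractions, `maturity_level`, `a_norm`, and the six traits.
#' @export
predict_integrated <- function(env_models, maturity_model, quality_model,
                               anorm_proxy, window, horizon) {
  if (horizon < 1) abort("horizon must be >= 1.",
                         class = "ripecast_config_error")
  out <- vector("list", horizon)
  for (s in seq_len(horizon)) {
    env_next <- vapply(ENV_VARS, function(v) {
      predict_env(env_models[[v]], window[, 1:3, drop = FALSE])
    }, numeric(1))
    frac <- gruat_forward(maturity_model, window)
    a_n <- anorm_proxy(frac$red)
    q <- predict_quality(quality_model, a_n)
    out[[s]] <- dplyr::bind_cols(
      tibble::tibble(step = s, temperature = env_next[1],
                     humidity = env_next[2], radiation = env_next[3],
                     red = frac$red, yellow = frac$yellow,
                     green = frac$green,
                     maturity_level = grade_maturity(frac$red, frac$yellow),
                     a_norm = a_n),
      q)
    window <- rbind(window[-1, , drop = FALSE],
                    c(env_next, frac$red, frac$yellow, frac$green))
  }
  dplyr::bind_rows(out)
}

#' Save / load a model checkpoint
#'
#' Portable JSON container holding the model class, configuration, weights
#' at full precision, loss history, and any attached scalers.
#'
#' @param model A `ripecast_model` (env LSTM, GRU-AT, or quality DNN).
#' @param path Checkpoint path (.json).
#' @export
save_checkpoint <- function(model, path) {
  payload <- list(
    class = class(model),
    config = unclass(model$config),
    params = lapply(model$params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
      else list(dim = NULL, data = as.numeric(p))
    }),
    weights = model$weights,
    history = model$history,
    scaler = if (!is.null(model$scaler)) unclass(model$scaler),
    scalers = if (!is.null(model$scalers)) unclass(model$scalers)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(payload$params, function(p) {
    if (!is.null(p$dim) && length(p$dim) == 2) {
      matrix(p$data, p$dim[1], p$dim[2])
    } else as.numeric(p$data)
  })
  config_class <- switch(payload$class[1],
                         env_lstm = "env_config",
                         gruat_model = "maturity_config",
                         quality_dnn = "quality_config")
  model <- list(config = structure(as.list(payload$config),
                                   class = config_class),
                params = params,
                history = tibble::as_tibble(payload$history))
  if (!is.null(payload$weights)) model$weights <- payload$weights
  if (!is.null(payload$scaler)) {
    model$scaler <- structure(tibble::as_tibble(payload$scaler),
                              class = c("minmax_scaler", "tbl_df", "tbl",
                                        "data.frame"))
  }
  if (!is.null(payload$scalers)) {
    model$scalers <- tibble::as_tibble(payload$scalers)
  }
  structure(model, class = payload$class)
}

#' Published image distribution worked example
#'
#' The per-stage image counts of the source campaign (1606 fruit images over
#' the five maturity stages) with stage percentages recomputed from the
#' counts.
#'
#' @return Tibble with `maturity_level`, `stage`, `n_images`, and recomputed
#'   `percentage` (one decimal).
#' @export
maturity_image_distribution <- function() {
  counts <- c(626L, 266L, 166L, 146L, 402L)
  tibble::tibble(
    maturity_level = 1:5,
    stage = c("green ripening", "transition", "early ripening",
              "mid-ripening", "late ripening"),
    n_images = counts,
    percentage = round(100 * counts / sum(counts), 1))
}
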