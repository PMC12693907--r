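# Desk-scale recovery experiments on the simulator. Each experiment builds a
# noiseless (unless stated) scenario, trains the relevant stage at reduced
# size, and reports held-out metrics. The model architectures and training
# lengths here are deliberately smaller than the full-campaign defaults so
# an experiment runs in minutes on one core; the signal is noiseless, so
# capacity, not size, is what is being checked.

#' Environment forecaster recovery on a noiseless diurnal series
#'
#' Simulates a noiseless greenhouse series, preprocesses and windows it
#' (T = 24), trains a reduced temperature LSTM (1 layer x 32 units) on the
#' earliest 80% of windows and evaluates next-step predictions on the final
#' 20% (later in time).
#'
#' @param seed Integer seed.
#' @param days Days of simulated series (default 12).
#' @param epochs Training epochs (default 40).
#' @return List with `metrics` (tibble: per-variable R2/MAE/RMSE in physical
#'   units for temperature), `model`, and `scaler`.
#' @export
experiment_env_recovery <- function(seed = 1L, days = 12, epochs = 40) {
  scenario <- sim_scenario(temp_sigma = 0, hum_sigma = 0, rad_sigma = 0,
                           missing_rate = 0, seed = seed)
  env <- gen_environment(scenario, days = days)
  prep <- preprocess_sensors(env)
  data <- windowize(prep$scaled, 24, vars = ENV_VARS)
  n <- dim(data$windows)[1]
  n_train <- floor(0.8 * n)
  train <- list(windows = data$windows[1:n_train, , , drop = FALSE],
                targets = data$targets[1:n_train, , drop = FALSE],
                vars = data$vars)
  test_idx <- (n_train + 1):n
  config <- env_config("temperature", layers = 1, hidden = 32,
                       epochs = epochs, seed = seed)
  model <- build_env_model(config)
  model <- train_env(model, train, scaler = prep$scaler)
  pred_scaled <- predict_env(model, data$windows[test_idx, , , drop = FALSE])
  truth <- unscale_var(data$targets[test_idx, 1], prep$scaler, "temperature")
  pred <- unscale_var(pred_scaled, prep$scaler, "temperature")
  list(metrics = metric_report(tibble::tibble(temperature = truth),
                               tibble::tibble(temperature = pred),
                               model = "lstm", split = "holdout"),
       model = model, scaler = prep$scaler)
}

#' Ripeness model recovery on noiseless color kinetics
#'
#' Simulates noiseless logistic green-to-red kinetics for a small plant
#' cohort, assembles the six-channel windows, trains a reduced GRU-AT model
#' on the train-split plants and evaluates next-step fraction predictions on
#' the held-out test plants.
#'
#' @param seed Integer seed.
#' @param n_plants Cohort size (default 10).
#' @param epochs Training epochs (default 40).
#' @param stride Keep every `stride`-th window (default 4).
#' @return List with `metrics` (R2/MAE/RMSE for red, yellow, green),
#'   `model`, `scaler`, and the assembled datasets.
#' @export
experiment_maturity_recovery <- function(seed = 1L, n_plants = 10,
                                         epochs = 40, stride = 4) {
  scenario <- sim_scenario(n_plants = n_plants, days = 21, stagger_days = 4,
                           temp_sigma = 0, hum_sigma = 0, rad_sigma = 0,
                           missing_rate = 0, gdd50_sd = 4, seed = seed)
  env <- gen_environment(scenario)
  prep <- preprocess_sensors(env)
  n_steps <- round(scenario$days * 24 / scenario$step_hours)
  offsets <- withr::with_seed(scenario$seed + 1L, {
    off <- round(seq(0, scenario$stagger_days * 24,
                     length.out = n_plants))
    list(off = off, gdd50 = scenario$gdd50 + rnorm(n_plants, 0, scenario$gdd50_sd))
  })
  colors <- purrr::map_dfr(seq_len(n_plants), function(i) {
    slice <- env[(offsets$off[i] + 1):(offsets$off[i] + n_steps), ]
    traj <- gen_color_trajectory(slice, scenario, gdd50 = offsets$gdd50[i])
    dplyr::bind_cols(tibble::tibble(plant_id = sprintf("P%03d", i)), traj)
  })
  data <- assemble_maturity_dataset(prep$scaled, colors, T_steps = 24)
  keep <- seq(1, dim(data$windows)[1], by = stride)
  data <- list(windows = data$windows[keep, , , drop = FALSE],
               targets = data$targets[keep, , drop = FALSE],
               plant = data$plant[keep], vars = data$vars)
  split <- split_by_plant(colors, seed = seed)
  test_plants <- split$plant_id[split$split == "test"]
  is_test <- data$plant %in% test_plants
  train <- list(windows = data$windows[!is_test, , , drop = FALSE],
                targets = data$targets[!is_test, , drop = FALSE])
  config <- maturity_config(hidden = 32, att_dim = 16, fc = 16,
                            epochs = epochs, seed = seed)
  model <- build_maturity_model(config)
  model <- train_maturity(model, train)
  pred <- predict_maturity(model, data$windows[is_test, , , drop = FALSE])
  truth <- tibble::as_tibble(data$targets[is_test, , drop = FALSE],
                             .name_repair = ~ c("red", "yellow", "green"))
  list(metrics = metric_report(truth, pred, model = "gru_at",
                               split = "test-plants"),
       model = model, scaler = prep$scaler, colors = colors, split = split)
}

#' Quality DNN recovery on noiseless trait responses
#'
#' Draws a* features over the fruit's observed range, generates traits from
#' the simulator's response curves with noise `sigma_scale` times the
#' scenario trait SDs (0 = noiseless), trains the DNN (dropout disabled for
#' the noiseless capacity check) and evaluates per-trait R2 on a 25%
#' holdout.
#'
#' @param seed Integer seed.
#' @param n Sample size (default 320).
#' @param sigma_scale Trait noise multiplier (default 0).
#' @param epochs Training epochs (default 300).
#' @param dropout Hidden-layer dropout during training (default 0 here; the
#'   full-campaign default is 0.4).
#' @return List with `metrics`, `model`, and the train/test frames.
#' @export
experiment_quality_recovery <- function(seed = 1L, n = 320, sigma_scale = 0,
                                        epochs = 300, dropout = 0) {
  scenario <- sim_scenario(seed = seed)
  scenario$trait_sigma <- scenario$trait_sigma * sigma_scale
  a_norm <- withr::with_seed(seed, runif(n, 0.40, 0.68))
  traits <- gen_quality(a_norm, scenario, seed = seed + 1L)
  idx_test <- withr::with_seed(seed + 2L, sample.int(n, round(0.25 * n)))
  config <- quality_config(epochs = epochs, dropout = dropout, seed = seed)
  model <- build_quality_model(config)
  model <- train_quality(model, a_norm[-idx_test], traits[-idx_test, ])
  pred <- predict_quality(model, a_norm[idx_test])
  list(metrics = metric_report(traits[idx_test, ], pred, model = "dnn",
                               split = "holdout"),
       model = model,
       a_norm = a_norm, traits = traits, idx_test = idx_test)
}

#' Integrated end-to-end recovery on held-out plants
#'
#' Simulates a noiseless campaign with rendered fruit images, trains all
#' three stages on the train-split plants, calibrates the red-fraction to
#' a* proxy, then rolls the integrated pipeline forward over each held-out
#' plant's season from its first day of history and scores the predicted
#' LYC against the trait values implied by the plant's true color course.
#'
#' @param seed Integer seed.
#' @param n_plants Cohort size (default 10).
#' @return List with `metrics` (per-trait R2 for the integrated rollout,
#'   pooled over held-out plants), `rollouts` (per-plant prediction
#'   tibbles), and the fitted stage models.
#' @export
experiment_integrated <- function(seed = 1L, n_plants = 10) {
  scenario <- sim_scenario(n_plants = n_plants, days = 18, stagger_days = 4,
                           temp_sigma = 0, hum_sigma = 0, rad_sigma = 0,
                           missing_rate = 0, gdd50_sd = 4,
                           trait_sigma = c(FI = 0, SSC = 0, SS = 0,
                                           TA = 0, VC = 0, LYC = 0),
                           seed = seed)
  sim <- simulate_dataset(scenario)
  prep <- preprocess_sensors(sim$env)
  split <- split_by_plant(sim$colors, seed = seed)
  test_plants <- split$plant_id[split$split == "test"]

  # stage 1: environment forecasters (reduced, shared series)
  env_data <- windowize(prep$scaled, 24, vars = ENV_VARS)
  env_models <- lapply(setNames(ENV_VARS, ENV_VARS), function(v) {
    cfg <- env_config(v, layers = 1, hidden = 32, epochs = 100,
                      lr_final = 2e-4, seed = seed)
    train_env(build_env_model(cfg), env_data, scaler = prep$scaler)
  })

  # stage 2: ripeness GRU-AT on train plants (all windows; one-step accuracy
  # governs the multi-day rollout)
  mat_data <- assemble_maturity_dataset(prep$scaled, sim$colors, T_steps = 24)
  is_train <- !(mat_data$plant %in% test_plants)
  mat_train <- list(
    windows = mat_data$windows[is_train, , , drop = FALSE],
    targets = mat_data$targets[is_train, , drop = FALSE])
  mat_model <- build_maturity_model(
    maturity_config(hidden = 32, att_dim = 16, fc = 16, epochs = 200,
                    lr_final = 5e-5, seed = seed))
  mat_model <- train_maturity(mat_model, mat_train)

  # stage 3: quality DNN + proxy on train plants' fruit observations
  fruit_train <- sim$fruit[!(sim$fruit$plant_id %in% test_plants), ]
  q_model <- build_quality_model(quality_config(epochs = 120, dropout = 0,
                                                seed = seed))
  q_model <- train_quality(q_model, fruit_train$a_norm, fruit_train)
  proxy <- fit_anorm_proxy(fruit_train$red_meas, fruit_train$a_norm)

  # integrated rollout over each held-out plant
  joined <- dplyr::inner_join(sim$colors, prep$scaled, by = "timestamp")
  rollouts <- purrr::map(test_plants, function(p) {
    pj <- joined[joined$plant_id == p, ]
    window <- as.matrix(pj[1:24, c(ENV_VARS, "red", "yellow", "green")])
    horizon <- nrow(pj) - 24
    pred <- predict_integrated(env_models, mat_model, q_model, proxy,
                               window, horizon)
    pred$timestamp <- pj$timestamp[25:nrow(pj)]
    pred$plant_id <- p
    pred
  })
  pred_all <- dplyr::bind_rows(rollouts)
  # ground truth at image times: traits implied by the plant's true a_norm
  fruit_test <- sim$fruit[sim$fruit$plant_id %in% test_plants, ]
  eval_df <- dplyr::inner_join(
    fruit_test[, c("plant_id", "timestamp", QUALITY_TRAITS)],
    pred_all[, c("plant_id", "timestamp", QUALITY_TRAITS)],
    by = c("plant_id", "timestamp"), suffix = c("_true", "_pred"))
  truth <- eval_df[, paste0(QUALITY_TRAITS, "_true")]
  est <- eval_df[, paste0(QUALITY_TRAITS, "_pred")]
  names(truth) <- names(est) <- QUALITY_TRAITS
  list(metrics = metric_report(truth, est, model = "integrated",
                               split = "test-plants"),
       rollouts = rollouts, env_models = env_models,
       maturity_model = mat_model, quality_model = q_model, proxy = proxy,
       sim = sim, split = split)
}
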