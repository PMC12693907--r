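# Synthetic greenhouse simulator: diurnal microclimate with AR(1) noise and
# missingness, thermal-time (GDD) driven green->red color kinetics with a
# transient yellow phase, fruit disc rendering for the image pipeline, and
# quality traits generated as smooth functions of the normalized a* feature.

#' Simulation scenario
#'
#' Defines the study conditions the simulator emulates: an hourly-logged
#' greenhouse monitored over a ripening campaign of 80 plants, diurnal
#' temperature/humidity/radiation with autocorrelated noise, ripening driven
#' by growing degree days (GDD) above a base temperature, and six quality
#' traits responding smoothly to the fruit's normalized a* color feature.
#'
#' @param n_plants Number of monitored plants (default 80).
#' @param days Ripening span monitored per plant, days (default 21).
#' @param step_hours Logging interval (default 1 hour, so a 24-step window
#'   spans one day).
#' @param stagger_days Plants start ripening spread uniformly over this many
#'   days (default 7), giving the later-starting plants used as the
#'   temporally gapped test set.
#' @param temp_mean,temp_amp,temp_sigma Temperature mean, diurnal amplitude
#'   (peak 14:00) and AR(1) noise SD, degrees C.
#' @param hum_mean,hum_amp,hum_sigma Humidity (anti-phase with temperature),
#'   %RH.
#' @param rad_peak,day_length,rad_sigma Solar radiation peak (W/m2),
#'   day length in hours (daylight centered on noon), truncated noise SD.
#' @param t_base Base temperature for GDD accumulation, degrees C.
#' @param gdd50 Thermal time (degree-days) at which the red fraction reaches
#'   0.5.
#' @param gdd50_sd Between-plant SD of `gdd50`.
#' @param steepness Logistic steepness of the red fraction in GDD units.
#' @param yellow_amp,yellow_width Amplitude and GDD width of the transient
#'   yellow phase.
#' @param trait_sigma Named numeric vector of additive noise SDs for the six
#'   traits (trait units).
#' @param missing_rate,missing_max_run Missingness injected into the sensor
#'   series: overall rate and maximum run length.
#' @param image_every_hours Interval between rendered fruit images.
#' @param image_size Rendered image side, pixels.
#' @param start First timestamp of the campaign (UTC).
#' @param seed Master seed.
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(n_plants = 80, days = 21, step_hours = 1,
                         stagger_days = 7,
                         temp_mean = 22, temp_amp = 5, temp_sigma = 0.5,
                         hum_mean = 75, hum_amp = 15, hum_sigma = 2,
                         rad_peak = 600, day_length = 12, rad_sigma = 20,
                         t_base = 10, gdd50 = 130, gdd50_sd = 6,
                         steepness = 0.04,
                         yellow_amp = 0.35, yellow_width = 40,
                         trait_sigma = c(FI = 0.3, SSC = 0.15, SS = 1.0,
                                         TA = 0.02, VC = 0.01, LYC = 0.004),
                         missing_rate = 0.03, missing_max_run = 4,
                         image_every_hours = 24, image_size = 64,
                         start = as.POSIXct("2024-05-01 00:00:00", tz = "UTC"),
                         seed = 42L) {
  stopifnot(temp_sigma >= 0, hum_sigma >= 0, rad_sigma >= 0,
            day_length > 0, day_length < 24, steepness > 0,
            missing_rate >= 0, missing_rate < 1)
  structure(as.list(environment()), class = "sim_scenario")
}

# Trait response curves: smooth functions of a_norm in [0, 1]. LYC, SSC and
# SS rise with redness (saturating logistic), FI and TA fall, VC is concave
# (rise then fall). Ranges are typical of greenhouse tomato.
TRAIT_CURVES <- list(
  FI  = list(shape = "logistic", base = 2.0,  amp = 4.5,   mid = 0.54, k = 40, dir = -1),
  SSC = list(shape = "logistic", base = 4.0,  amp = 2.0,   mid = 0.54, k = 40, dir = +1),
  SS  = list(shape = "logistic", base = 15.0, amp = 15.0,  mid = 0.54, k = 40, dir = +1),
  TA  = list(shape = "logistic", base = 0.30, amp = 0.30,  mid = 0.54, k = 40, dir = -1),
  VC  = list(shape = "peak",     base = 0.10, amp = 0.15,  mid = 0.54, w = 0.06),
  LYC = list(shape = "logistic", base = 0.005, amp = 0.085, mid = 0.54, k = 40, dir = +1)
)

#' Noiseless trait response to the a* feature
#'
#' The closed-form curves the simulator samples around: saturating logistics
#' (rising for SSC/SS/LYC, falling for FI/TA) and a concave peak for VC. At
#' `a_norm = mid` a logistic trait sits exactly at `base + amp/2` and VC at
#' `base + amp`.
#'
#' @param a_norm Numeric vector in \[0, 1\].
#' @param trait One of `"FI"`, `"SSC"`, `"SS"`, `"TA"`, `"VC"`, `"LYC"`.
#' @return Numeric vector of trait values (trait units).
#' @export
quality_response <- function(a_norm, trait) {
  cv <- TRAIT_CURVES[[trait]]
  if (is.null(cv)) abort(sprintf("unknown trait '%s'.", trait))
  if (cv$shape == "logistic") {
    f <- 1 / (1 + exp(-cv$k * (a_norm - cv$mid)))
    if (cv$dir < 0) f <- 1 - f
    cv$base + cv$amp * f
  } else {
    cv$base + cv$amp * exp(-((a_norm - cv$mid) / cv$w)^2)
  }
}

ar1_noise <- function(n, sigma, rho = 0.8) {
  if (sigma == 0) return(numeric(n))
  z <- rnorm(n)
  e <- numeric(n)
  e[1] <- sigma * z[1]
  scale <- sigma * sqrt(1 - rho^2)
  for (i in seq_len(n)[-1]) e[i] <- rho * e[i - 1] + scale * z[i]
  e
}

#' Generate a greenhouse environment series
#'
#' Temperature is a diurnal sinusoid (peak 14:00) plus AR(1) noise; humidity
#' is anti-phase, clamped to \[0, 100\]; radiation is a half-sine over the
#' daylight window (zero at night) with noise truncated at zero.
#'
#' @param scenario A [sim_scenario()].
#' @param days Number of days (default `scenario$days + scenario$stagger_days`
#'   so every plant's span is covered).
#' @param seed Seed (default the scenario's).
#' @return Tibble with `timestamp`, `temperature`, `humidity`, `radiation`.
#' @export
gen_environment <- function(scenario, days = NULL, seed = NULL) {
  days <- days %||% (scenario$days + scenario$stagger_days)
  seed <- seed %||% scenario$seed
  n <- round(days * 24 / scenario$step_hours)
  h <- (seq_len(n) - 1) * scenario$step_hours
  hod <- h %% 24
  diurnal <- sin(2 * pi * (hod - 8) / 24)
  withr::with_seed(seed, {
    temp <- scenario$temp_mean + scenario$temp_amp * diurnal +
      ar1_noise(n, scenario$temp_sigma)
    hum <- scenario$hum_mean - scenario$hum_amp * diurnal +
      ar1_noise(n, scenario$hum_sigma)
    hum <- pmin(pmax(hum, 0), 100)
    sunrise <- 12 - scenario$day_length / 2
    daylight <- hod >= sunrise & hod <= sunrise + scenario$day_length
    rad <- ifelse(daylight,
                  scenario$rad_peak *
                    sin(pi * (hod - sunrise) / scenario$day_length), 0)
    if (scenario$rad_sigma > 0) {
      rad[daylight] <- pmax(rad[daylight] +
                              rnorm(sum(daylight), 0, scenario$rad_sigma), 0)
    }
  })
  tibble::tibble(
    timestamp = scenario$start + h * 3600,
    temperature = temp, humidity = hum, radiation = rad)
}

#' Color kinetics driven by thermal time
#'
#' Accumulates growing degree days `GDD(t) = sum(max(T - t_base, 0) dt/24)`
#' over the environment series and maps them to surface fractions: red is a
#' logistic in GDD with midpoint `gdd50`; yellow is a transient Gaussian
#' bump around the midpoint capped so `red + yellow <= 1`; green is the
#' remainder. Fractions sum to 1 at every time and red is non-decreasing
#' whenever temperature stays at or above `t_base`.
#'
#' @param env Environment tibble (at least `timestamp`, `temperature`)
#'   covering the ripening span (one day or more).
#' @param scenario A [sim_scenario()].
#' @param gdd50 Per-plant midpoint override.
#' @return Tibble with `timestamp`, `gdd`, `red`, `yellow`, `green`.
#' @export
gen_color_trajectory <- function(env, scenario, gdd50 = scenario$gdd50) {
  if (nrow(env) < 24 / scenario$step_hours) {
    abort("environment series must cover at least one day.")
  }
  gdd <- cumsum(pmax(env$temperature - scenario$t_base, 0) *
                  scenario$step_hours / 24)
  red <- 1 / (1 + exp(-scenario$steepness * (gdd - gdd50)))
  yellow <- pmin(scenario$yellow_amp *
                   exp(-((gdd - gdd50) / scenario$yellow_width)^2),
                 1 - red)
  tibble::tibble(timestamp = env$timestamp, gdd = gdd, red = red,
                 yellow = yellow, green = 1 - red - yellow)
}

#' Quality traits from the a* feature
#'
#' Samples each trait around its [quality_response()] curve with additive
#' Gaussian noise (`scenario$trait_sigma`), clamped at zero.
#'
#' @param a_norm Numeric vector in \[0, 1\].
#' @param scenario A [sim_scenario()].
#' @param seed Seed (default the scenario's).
#' @return Tibble with columns `FI`, `SSC`, `SS`, `TA`, `VC`, `LYC`.
#' @export
gen_quality <- function(a_norm, scenario, seed = NULL) {
  seed <- seed %||% scenario$seed
  withr::with_seed(seed, {
    out <- purrr::map_dfc(QUALITY_TRAITS, function(tr) {
      v <- quality_response(a_norm, tr) +
        rnorm(length(a_norm), 0, scenario$trait_sigma[[tr]])
      tibble::tibble(!!tr := pmax(v, 0))
    })
  })
  out
}

# Base sector colors chosen so hue (with +/- 12 jitter) stays inside the
# classifier's bands: red ~0 deg, yellow ~47 deg, green ~124 deg.
SECTOR_RGB <- list(red = c(200, 40, 40), yellow = c(235, 200, 40),
                   green = c(60, 170, 60))

#' Render a synthetic fruit disc
#'
#' Draws a disc on a neutral gray background with angular sectors colored
#' red/yellow/green in the given proportions, plus small per-pixel channel
#' jitter. [color_ratios()] on the rendered image recovers the input
#' fractions to about the pixel-discretization error.
#'
#' @param red,yellow,green Target fractions (must sum to 1).
#' @param size Image side in pixels.
#' @param seed Seed for the jitter.
#' @return List with `image` (size x size x 3, 8-bit) and `mask` (logical).
#' @export
render_fruit_image <- function(red, yellow, green, size = 64, seed = 1L) {
  if (abs(red + yellow + green - 1) > 1e-6 || min(red, yellow, green) < -1e-9) {
    abort("fractions must be nonnegative and sum to 1.")
  }
  ctr <- (size + 1) / 2
  radius <- 0.42 * size
  xs <- matrix(rep(seq_len(size), each = size), size)   # column index
  ys <- matrix(rep(seq_len(size), times = size), size)  # row index
  inside <- (xs - ctr)^2 + (ys - ctr)^2 <= radius^2
  theta <- (atan2(ys - ctr, xs - ctr) + pi) / (2 * pi)  # in [0, 1)
  img <- array(180, c(size, size, 3))
  cls <- ifelse(theta < red, "red", ifelse(theta < red + yellow, "yellow",
                                           "green"))
  withr::with_seed(seed, {
    for (cname in names(SECTOR_RGB)) {
      sel <- inside & cls == cname
      npx <- sum(sel)
      if (npx == 0) next
      for (ch in 1:3) {
        base <- SECTOR_RGB[[cname]][ch]
        layer <- img[, , ch]
        layer[sel] <- pmin(pmax(round(base + runif(npx, -12, 12)), 0), 255)
        img[, , ch] <- layer
      }
    }
  })
  list(image = img, mask = inside)
}

#' Inject missing runs into a sensor series
#'
#' Masks values in runs of length up to `max_run`, per variable, targeting
#' the requested overall rate. When `max_run > 5` at least one run longer
#' than 5 points is planted so the historical fill branch is exercised. The
#' first day is left intact (a historical fill needs a prior day).
#'
#' @param data Sensor tibble.
#' @param rate Fraction of points to mask, in \[0, 1).
#' @param max_run Maximum run length.
#' @param seed Seed.
#' @param vars Variables to mask.
#' @return Tibble with `NA` runs injected.
#' @export
inject_missingness <- function(data, rate = 0.03, max_run = 4, seed = 1L,
                               vars = sensor_vars(data)) {
  if (rate >= 1 || rate < 0) abort("rate must be in [0, 1).")
  if (rate == 0) return(data)
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  first_ok <- ceiling(24 / 1) + 1 # keep day one observed
  withr::with_seed(seed, {
    for (v in vars) {
      miss <- rep(FALSE, n)
      if (max_run > 5) {
        st <- sample(first_ok:(n - max_run), 1)
        miss[st:(st + max_run - 1)] <- TRUE
      }
      budget <- max(round(rate * n) - sum(miss), 0)
      guard <- 0
      while (budget > 0 && guard < 10000) {
        len <- min(sample.int(max_run, 1), budget)
        st <- sample(first_ok:(n - len), 1)
        span <- st:(st + len - 1)
        if (!any(miss[span])) {
          miss[span] <- TRUE
          budget <- budget - len
        }
        guard <- guard + 1
      }
      data[[v]][miss] <- NA_real_
    }
  })
  data
}

#' Simulate a full multi-plant campaign
#'
#' Generates the shared greenhouse series, per-plant staggered color
#' trajectories (with between-plant `gdd50` variation), rendered fruit
#' images at the imaging interval measured through the image pipeline
#' ([gray_world_balance()], [rgb_to_a()], [color_ratios()],
#' [grade_maturity()]), and quality traits from the measured a* feature.
#'
#' @param scenario A [sim_scenario()].
#' @param render_images If `FALSE`, skip rendering and derive `a_norm`
#'   analytically from the color fractions (faster; image pipeline not
#'   exercised).
#' @return List with `env` (sensor tibble over the whole campaign),
#'   `plants` (plant metadata), `colors` (hourly fractions per plant), and
#'   `fruit` (per-image observations joined with quality traits).
#' @export
simulate_dataset <- function(scenario = sim_scenario(), render_images = TRUE) {
  env <- gen_environment(scenario)
  n_steps_plant <- round(scenario$days * 24 / scenario$step_hours)
  offsets <- withr::with_seed(scenario$seed + 1L, {
    off <- round(seq(0, scenario$stagger_days * 24,
                     length.out = scenario$n_plants) / scenario$step_hours)
    jit <- rnorm(scenario$n_plants, 0, scenario$gdd50_sd)
    list(off = off, gdd50 = scenario$gdd50 + jit)
  })
  plants <- tibble::tibble(
    plant_id = sprintf("P%03d", seq_len(scenario$n_plants)),
    offset_steps = offsets$off, gdd50 = offsets$gdd50)
  colors <- purrr::pmap_dfr(plants, function(plant_id, offset_steps, gdd50) {
    slice <- env[(offset_steps + 1):(offset_steps + n_steps_plant), ]
    traj <- gen_color_trajectory(slice, scenario, gdd50 = gdd50)
    dplyr::bind_cols(tibble::tibble(plant_id = plant_id), traj)
  })
  every <- max(1, round(scenario$image_every_hours / scenario$step_hours))
  obs_idx <- seq(1, n_steps_plant, by = every)
  fruit <- purrr::map_dfr(seq_len(nrow(plants)), function(i) {
    pc <- colors[colors$plant_id == plants$plant_id[i], ][obs_idx, ]
    if (render_images) {
      meas <- purrr::map_dfr(seq_len(nrow(pc)), function(j) {
        fr <- render_fruit_image(pc$red[j], pc$yellow[j], pc$green[j],
                                 size = scenario$image_size,
                                 seed = scenario$seed + 1000L * i + j)
        bal <- gray_world_balance(fr$image)$image
        a <- rgb_to_a(bal, fr$mask)
        cr <- color_ratios(bal, fr$mask)
        tibble::tibble(a_mean = a$a_mean, a_norm = a$a_norm,
                       red_meas = cr$red, yellow_meas = cr$yellow,
                       green_meas = cr$green)
      })
    } else {
      # analytic surrogate: a* interpolated between sector-color a* values
      a_red <- pixel_a_star(200, 40, 40)
      a_yel <- pixel_a_star(235, 200, 40)
      a_grn <- pixel_a_star(60, 170, 60)
      a_mean <- pc$red * a_red + pc$yellow * a_yel + pc$green * a_grn
      meas <- tibble::tibble(a_mean = a_mean, a_norm = (a_mean + 128) / 255,
                             red_meas = pc$red, yellow_meas = pc$yellow,
                             green_meas = pc$green)
    }
    q <- gen_quality(meas$a_norm, scenario,
                     seed = scenario$seed + 7919L * i)
    dplyr::bind_cols(
      tibble::tibble(plant_id = plants$plant_id[i], timestamp = pc$timestamp),
      meas,
      tibble::tibble(maturity_level = grade_maturity(meas$red_meas,
                                                     meas$yellow_meas)),
      q)
  })
  list(env = env, plants = plants, colors = colors, fruit = fruit,
       scenario = scenario)
}

#' Windowed dataset grouped by plant
#'
#' Builds stride-1 windows within each plant's series (never across plants)
#' and concatenates them, keeping the plant of each window.
#'
#' @param data Tibble with `plant_id` and feature columns, time-ordered
#'   within plant.
#' @param T_steps Window length.
#' @param vars Feature columns (window channels).
#' @param target_vars Columns of the next-step target (default `vars`).
#' @return List with `windows` (S x T x X), `targets` (S x length(target_vars)),
#'   `plant` (length-S character), `vars`.
#' @export
windowize_by_plant <- function(data, T_steps, vars,
                               target_vars = vars) {
  parts <- split(tibble::as_tibble(data), data$plant_id)
  ws <- list(); ts <- list(); pl <- list()
  for (p in names(parts)) {
    df <- parts[[p]]
    if (nrow(df) < T_steps + 1) next
    m <- as.matrix(df[, vars])
    wd <- windowize(m, T_steps)
    tgt <- as.matrix(df[, target_vars])[(T_steps + 1):nrow(df), , drop = FALSE]
    ws[[p]] <- wd$windows
    ts[[p]] <- tgt
    pl[[p]] <- rep(p, dim(wd$windows)[1])
  }
  if (length(ws) == 0) {
    abort("no plant series long enough to window.",
          class = "ripecast_empty_dataset")
  }
  windows <- do.call(abind_first, ws)
  list(windows = windows, targets = do.call(rbind, ts),
       plant = unlist(pl, use.names = FALSE), vars = vars)
}

# rbind for (S, T, X) arrays along the first axis.
abind_first <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  total <- sum(vapply(arrs, function(a) dim(a)[1], integer(1)))
  out <- array(NA_real_, c(total, d[2], d[3]))
  at <- 0
  for (a in arrs) {
    s <- dim(a)[1]
    out[(at + 1):(at + s), , ] <- a
    at <- at + s
  }
  out
}
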