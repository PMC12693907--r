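# Sensor time-series preprocessing: box-plot outlier screening, two-branch gap
# filling (short gaps by linear interpolation, long gaps from a weather-matched
# historical day), min-max scaling, plant-wise splitting with a temporal gap,
# and sliding-window dataset construction.

#' Box-plot outlier bounds
#'
#' Computes the Tukey box-plot fences `Q1 - 1.5*IQR` and `Q3 + 1.5*IQR`, with
#' quartiles under the sorted-order linear-interpolation convention
#' (R's default type-7 quantiles). Values outside the fences are treated as
#' outliers by [qc_outliers()].
#'
#' @param values Numeric vector with at least 4 finite values.
#' @return Named numeric vector with elements `lower` and `upper`.
#' @examples
#' boxplot_bounds(c(2, 4, 6, 8, 100)) # c(lower = -2, upper = 14)
#' @export
boxplot_bounds <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 4) {
    abort("boxplot_bounds() needs at least 4 finite values.",
          class = "ripecast_degenerate_input")
  }
  q <- quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  c(lower = q[1] - 1.5 * iqr, upper = q[2] + 1.5 * iqr)
}

#' Flag box-plot outliers as missing
#'
#' Screens each sensor variable over the full series (before any splitting)
#' and replaces values outside the box-plot fences with `NA`.
#'
#' @param data Data frame with a `timestamp` column and numeric variables.
#' @param vars Character vector of variable columns; default all numeric
#'   columns except `timestamp`.
#' @return A tibble like `data` with outliers set to `NA` and a `"qc_report"`
#'   attribute (one row per variable: bounds and flag count).
#' @export
qc_outliers <- function(data, vars = sensor_vars(data)) {
  data <- tibble::as_tibble(data)
  report <- purrr::map_dfr(vars, function(v) {
    b <- boxplot_bounds(data[[v]])
    out <- !is.na(data[[v]]) & (data[[v]] < b["lower"] | data[[v]] > b["upper"])
    data[[v]][out] <<- NA_real_
    tibble::tibble(variable = v, lower = b[["lower"]], upper = b[["upper"]],
                   n_flagged = sum(out))
  })
  attr(data, "qc_report") <- report
  data
}

sensor_vars <- function(data) {
  setdiff(names(data)[vapply(data, is.numeric, logical(1))],
          c("timestamp", "plant_id"))
}

# Hours since epoch for a timestamp column (POSIXct or numeric hours).
time_hours <- function(ts) {
  if (inherits(ts, "POSIXct")) as.numeric(ts) / 3600 else as.numeric(ts)
}

#' Fill missing sensor values
#'
#' Two-branch gap filling: runs of at most `max_linear_gap` consecutive
#' missing points bracketed by observations are filled by linear
#' interpolation between the bracketing points; longer runs (and edge runs
#' without a bracket) are copied from the nearest prior day whose daily mean
#' of the same variable lies within one standard deviation (of all daily
#' means) of the gap day's mean, ties resolved to the most recent day.
#'
#' @param data Data frame with `timestamp` (constant step) and variables.
#' @param vars Variables to fill; default all numeric sensor columns.
#' @param max_linear_gap Longest run filled by interpolation (default 5).
#' @param history Optional data frame of the same shape covering an earlier
#'   period, searched (together with the observed part of `data`) for
#'   matching days.
#' @return Tibble with no missing values in `vars` and a `"fill_report"`
#'   attribute counting interpolated and historically filled points.
#' @export
fill_gaps <- function(data, vars = sensor_vars(data), max_linear_gap = 5,
                      history = NULL) {
  data <- tibble::as_tibble(data)
  th <- time_hours(data$timestamp)
  if (length(th) > 1) {
    steps <- diff(th)
    if (any(steps <= 0) || max(abs(steps - steps[1])) > 1e-6) {
      abort("timestamps must be strictly increasing at a constant step.")
    }
  }
  pool <- if (is.null(history)) data else
    dplyr::bind_rows(tibble::as_tibble(history)[, names(data)], data)
  pool_th <- time_hours(pool$timestamp)
  report <- tibble::tibble(variable = character(), n_interpolated = integer(),
                           n_historical = integer())
  for (v in vars) {
    y <- data[[v]]
    filled <- fill_one_var(y, th, pool[[v]], pool_th, max_linear_gap)
    data[[v]] <- filled$y
    report <- dplyr::add_row(report, variable = v,
                             n_interpolated = filled$n_lin,
                             n_historical = filled$n_hist)
  }
  attr(data, "fill_report") <- report
  data
}

fill_one_var <- function(y, th, pool_y, pool_th, max_linear_gap) {
  n_lin <- 0L
  n_hist <- 0L
  r <- rle(is.na(y))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    i <- starts[k]; j <- ends[k]
    len <- j - i + 1L
    bracketed <- i > 1L && j < length(y)
    if (len <= max_linear_gap && bracketed) {
      ya <- y[i - 1L]; yb <- y[j + 1L]
      ta <- th[i - 1L]; tb <- th[j + 1L]
      y[i:j] <- ya + (yb - ya) * (th[i:j] - ta) / (tb - ta)
      n_lin <- n_lin + len
    } else {
      y[i:j] <- historical_fill(th[i:j], pool_y, pool_th)
      n_hist <- n_hist + len
    }
  }
  list(y = y, n_lin = n_lin, n_hist = n_hist)
}

# Fill the timestamps `gap_th` (hours) from the nearest prior day in the pool
# whose daily mean matches the gap day's mean within one SD of daily means.
historical_fill <- function(gap_th, pool_y, pool_th) {
  day <- floor(pool_th / 24)
  tod <- round(pool_th - day * 24, 6)
  obs <- !is.na(pool_y)
  dm <- tapply(pool_y[obs], day[obs], mean)
  if (length(dm) < 1) {
    abort("unfillable gap: no observed historical data.",
          class = "ripecast_unfillable_gap")
  }
  sd_dm <- stats::sd(dm)
  if (!is.finite(sd_dm) || sd_dm == 0) sd_dm <- Inf
  gap_day <- floor(gap_th[1] / 24)
  ref_days <- as.numeric(names(dm))
  # reference mean: the gap's own day if partly observed, else nearest day
  ref_idx <- if (any(ref_days == gap_day)) which(ref_days == gap_day) else
    which.min(abs(ref_days - gap_day))
  ref_mean <- dm[ref_idx]
  cand <- ref_days[ref_days < gap_day & abs(dm - ref_mean) < sd_dm]
  if (length(cand) == 0) cand <- ref_days[ref_days < gap_day]
  if (length(cand) == 0) {
    abort("unfillable gap: no prior day available for historical fill.",
          class = "ripecast_unfillable_gap")
  }
  vapply(gap_th, function(t1) {
    tod1 <- round(t1 - floor(t1 / 24) * 24, 6)
    for (d in sort(cand, decreasing = TRUE)) { # nearest prior first
      hit <- which(day == d & abs(tod - tod1) < 1e-6 & obs)
      if (length(hit) > 0) return(pool_y[hit[1]])
    }
    abort("unfillable gap: no matching time of day in historical data.",
          class = "ripecast_unfillable_gap")
  }, numeric(1))
}

#' Fit a per-variable min-max scaler
#'
#' @param data Data frame (usually the training split only).
#' @param vars Variables to scale.
#' @return A `minmax_scaler`: tibble with `variable`, `min`, `max`.
#' @export
minmax_scaler <- function(data, vars = sensor_vars(data)) {
  sc <- purrr::map_dfr(vars, function(v) {
    rng <- range(data[[v]], na.rm = TRUE)
    tibble::tibble(variable = v, min = rng[1], max = rng[2])
  })
  if (any(sc$max == sc$min)) {
    abort(paste0("degenerate scale (max == min) for: ",
                 paste(sc$variable[sc$max == sc$min], collapse = ", ")),
          class = "ripecast_degenerate_scale")
  }
  structure(sc, class = c("minmax_scaler", class(sc)))
}

#' Min-max scale to \[0, 1\]
#'
#' `y = (d - d_min) / (d_max - d_min)` per variable, with parameters fitted
#' on the training split. Out-of-range values are not clipped, so the
#' transform stays invertible.
#'
#' @param data Data frame containing the scaler's variables.
#' @param scaler A [minmax_scaler()].
#' @return Tibble with scaled variables.
#' @export
scale_minmax <- function(data, scaler) {
  data <- tibble::as_tibble(data)
  for (i in seq_len(nrow(scaler))) {
    v <- scaler$variable[i]
    data[[v]] <- (data[[v]] - scaler$min[i]) / (scaler$max[i] - scaler$min[i])
  }
  data
}

#' @rdname scale_minmax
#' @export
unscale_minmax <- function(data, scaler) {
  data <- tibble::as_tibble(data)
  for (i in seq_len(nrow(scaler))) {
    v <- scaler$variable[i]
    data[[v]] <- data[[v]] * (scaler$max[i] - scaler$min[i]) + scaler$min[i]
  }
  data
}

# Scalar helpers used by the models.
scale_var <- function(x, scaler, var) {
  i <- match(var, scaler$variable)
  (x - scaler$min[i]) / (scaler$max[i] - scaler$min[i])
}

unscale_var <- function(x, scaler, var) {
  i <- match(var, scaler$variable)
  x * (scaler$max[i] - scaler$min[i]) + scaler$min[i]
}

#' Plant-disjoint train/validation/test split with a temporal gap
#'
#' Assigns whole plants to train/validation/test in the given ratios
#' (largest-remainder rounding). The test set is formed from the plants whose
#' records start latest, so that test data lie after a temporal boundary; the
#' remaining plants are shuffled (seeded) between train and validation.
#' Train/validation records at or after the boundary (the earliest test
#' record) are flagged for exclusion so that no training record postdates the
#' test period's start.
#'
#' @param records Data frame with `plant_id` and `timestamp` columns.
#' @param ratios Length-3 numeric summing to 1 (default `c(0.7, 0.2, 0.1)`).
#' @param seed Integer seed for the train/validation shuffle.
#' @return A `split_assignment`: tibble with `plant_id` and `split`, plus
#'   attributes `boundary` (timestamp) and `ratios`.
#' @export
split_by_plant <- function(records, ratios = c(0.7, 0.2, 0.1), seed = 1L) {
  if (length(ratios) != 3 || abs(sum(ratios) - 1) > 1e-8) {
    abort("ratios must be three numbers summing to 1.",
          class = "ripecast_config_error")
  }
  plants <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(records), .data$plant_id),
    first = min(.data$timestamp), .groups = "drop"
  )
  n <- nrow(plants)
  if (n < 10) abort("need at least 10 plants to split.")
  counts <- largest_remainder(n, ratios)
  ord <- order(plants$first, plants$plant_id, decreasing = TRUE)
  test_ids <- plants$plant_id[ord[seq_len(counts[3])]]
  rest <- setdiff(plants$plant_id, test_ids)
  rest <- rest[withr::with_seed(seed, sample.int(length(rest)))]
  train_ids <- rest[seq_len(counts[1])]
  val_ids <- setdiff(rest, train_ids)
  asg <- tibble::tibble(
    plant_id = c(train_ids, val_ids, test_ids),
    split = rep(c("train", "validation", "test"), times = counts)
  )
  boundary <- min(records$timestamp[records$plant_id %in% test_ids])
  structure(asg, class = c("split_assignment", class(asg)),
            boundary = boundary, ratios = ratios, seed = seed)
}

largest_remainder <- function(n, ratios) {
  raw <- n * ratios
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    take <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[take] <- counts[take] + 1
  }
  as.integer(counts)
}

#' Apply a split assignment to records
#'
#' Joins the `split` label onto the records and flags train/validation
#' records that fall at or after the temporal boundary (`keep = FALSE`).
#'
#' @param records Data frame with `plant_id` and `timestamp`.
#' @param assignment A [split_by_plant()] result.
#' @return Tibble with added `split` and `keep` columns.
#' @export
apply_split <- function(records, assignment) {
  out <- dplyr::left_join(tibble::as_tibble(records),
                          tibble::as_tibble(assignment), by = "plant_id")
  boundary <- attr(assignment, "boundary")
  out$keep <- out$split == "test" | out$timestamp < boundary
  out
}

#' Sliding-window supervised dataset
#'
#' Builds stride-1 windows of `T` consecutive rows with the immediately
#' following row as the next-step target, giving `S = n - T` samples shaped
#' `(S, T, X)`.
#'
#' @param data Data frame of scaled numeric variables ordered in time (or a
#'   numeric matrix).
#' @param T_steps Window length (time steps).
#' @param vars Variable columns to include (default all numeric).
#' @return A `windowed_dataset`: list with `windows` (S x T x X array),
#'   `targets` (S x X matrix), and `vars`.
#' @export
windowize <- function(data, T_steps, vars = NULL) {
  m <- if (is.matrix(data)) data else {
    vars <- vars %||% sensor_vars(data)
    as.matrix(tibble::as_tibble(data)[, vars])
  }
  n <- nrow(m)
  x_dim <- ncol(m)
  if (n < T_steps + 1) {
    abort(sprintf("series length %d yields no windows for T = %d.", n, T_steps),
          class = "ripecast_empty_dataset")
  }
  s <- n - T_steps
  windows <- array(NA_real_, dim = c(s, T_steps, x_dim))
  for (t in seq_len(T_steps)) windows[, t, ] <- m[t:(t + s - 1), ]
  targets <- m[(T_steps + 1):n, , drop = FALSE]
  structure(list(windows = windows, targets = targets,
                 vars = colnames(m) %||% paste0("x", seq_len(x_dim))),
            class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf("<windowed_dataset> S = %d, T = %d, X = %d (%s)\n",
              d[1], d[2], d[3], paste(x$vars, collapse = ", ")))
  invisible(x)
}

#' Read / write sensor series CSV
#'
#' ISO-8601 `timestamp` column plus one numeric column per variable; missing
#' values are empty cells.
#'
#' @param path File path.
#' @return Tibble with a POSIXct `timestamp`.
#' @export
read_sensor_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC",
                             tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                            "%Y-%m-%d %H:%M:%S"))
  tibble::as_tibble(df)
}

#' @rdname read_sensor_csv
#' @param data Data frame with `timestamp` and variables.
#' @export
write_sensor_csv <- function(data, path) {
  out <- as.data.frame(data)
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a QC report as JSON
#'
#' Serializes the outlier and fill reports attached by [qc_outliers()] and
#' [fill_gaps()].
#'
#' @param data A tibble carrying `qc_report` / `fill_report` attributes.
#' @param path Output JSON path.
#' @export
write_qc_report <- function(data, path) {
  rep <- list(outliers = attr(data, "qc_report"),
              fills = attr(data, "fill_report"))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
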