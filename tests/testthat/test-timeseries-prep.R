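test_that("box-plot bounds match hand-computed quartile fences", {
  b <- boxplot_bounds(c(2, 4, 6, 8, 100))
  expect_equal(unname(b), c(-2, 14))
  expect_equal(unname(boxplot_bounds(c(5, 5, 5, 5))), c(5, 5))
  expect_equal(unname(boxplot_bounds(c(1, 2, 3, 4))), c(-0.5, 5.5))
  expect_error(boxplot_bounds(c(1, 2, 3)), class = "ripecast_degenerate_input")
})

test_that("box-plot bounds agree with a brute-force quantile oracle", {
  withr::with_seed(99, {
    for (i in 1:1000) {
      v <- rnorm(sample(4:12, 1), sd = sample(c(1, 10), 1))
      q1 <- oracle_quantile(v, 0.25)
      q3 <- oracle_quantile(v, 0.75)
      b <- boxplot_bounds(v)
      expect_equal(unname(b), c(q1 - 1.5 * (q3 - q1), q3 + 1.5 * (q3 - q1)),
                   tolerance = 1e-12)
    }
  })
})

test_that("outlier flagging replaces out-of-fence values with NA", {
  df <- tibble::tibble(timestamp = as.POSIXct("2024-05-01", tz = "UTC") +
                         3600 * (0:4),
                       temperature = c(2, 4, 6, 8, 100))
  out <- qc_outliers(df)
  expect_true(is.na(out$temperature[5]))
  expect_equal(out$temperature[1:4], c(2, 4, 6, 8))
  rep <- attr(out, "qc_report")
  expect_equal(rep$n_flagged, 1L)
})

make_series <- function(n_days, miss_at = integer()) {
  n <- n_days * 24
  h <- 0:(n - 1)
  y <- 20 + 5 * sin(2 * pi * (h %% 24 - 8) / 24)
  y[miss_at] <- NA
  tibble::tibble(timestamp = as.POSIXct("2024-05-01", tz = "UTC") + h * 3600,
                 temperature = y)
}

test_that("short gaps are filled by exact linear interpolation", {
  df <- tibble::tibble(
    timestamp = as.POSIXct("2024-05-01", tz = "UTC") + 3600 * (0:2),
    temperature = c(10, NA, 20))
  filled <- fill_gaps(df)
  expect_equal(filled$temperature[2], 15)
  # observed points untouched
  expect_equal(filled$temperature[c(1, 3)], c(10, 20))

  # a 4-point internal gap reproduces the exact linear segment
  df2 <- make_series(2, miss_at = 30:33)
  filled2 <- fill_gaps(df2)
  y <- make_series(2)$temperature
  seg <- y[29] + (y[34] - y[29]) * (1:4) / 5
  expect_equal(filled2$temperature[30:33], seg, tolerance = 1e-12)
  expect_equal(attr(filled2, "fill_report")$n_interpolated, 4L)
})

test_that("long gaps are copied from a weather-matched historical day", {
  # three identical diurnal days; a 6-point gap on day 3 must be filled with
  # the same clock hours from an earlier day, reproducing the cycle exactly
  df <- make_series(3, miss_at = 55:60)
  filled <- fill_gaps(df)
  truth <- make_series(3)$temperature
  expect_equal(filled$temperature[55:60], truth[55:60], tolerance = 1e-12)
  expect_equal(attr(filled, "fill_report")$n_historical, 6L)
})

test_that("gap filling leaves complete series unchanged and errors when unfillable", {
  df <- make_series(2)
  expect_equal(fill_gaps(df)$temperature, df$temperature)
  # all data missing: nothing to interpolate from
  df_bad <- tibble::tibble(
    timestamp = as.POSIXct("2024-05-01", tz = "UTC") + 3600 * (0:9),
    temperature = NA_real_)
  expect_error(fill_gaps(df_bad), class = "ripecast_unfillable_gap")
})

test_that("min-max scaling maps to [0,1], inverts exactly, and keeps out-of-range values unclipped", {
  df <- tibble::tibble(timestamp = as.POSIXct("2024-05-01", tz = "UTC") +
                         3600 * (0:2),
                       temperature = c(10, 20, 30))
  sc <- minmax_scaler(df)
  scaled <- scale_minmax(df, sc)
  expect_equal(scaled$temperature, c(0, 0.5, 1))
  back <- unscale_minmax(scaled, sc)
  expect_equal(back$temperature, df$temperature, tolerance = 1e-9)
  # Eq arithmetic beyond the fit range: (35-10)/(30-10) = 1.25
  expect_equal(scale_var(35, sc, "temperature"), 1.25)
  # degenerate scale
  df$temperature <- 7
  expect_error(minmax_scaler(df), class = "ripecast_degenerate_scale")
})

make_records <- function(n_plants, staggered = TRUE) {
  purrr::map_dfr(seq_len(n_plants), function(i) {
    start <- as.POSIXct("2024-05-01", tz = "UTC") +
      (if (staggered) (i - 1) * 86400 else 0)
    tibble::tibble(plant_id = sprintf("P%02d", i),
                   timestamp = start + 3600 * (0:47))
  })
}

test_that("plant split honors the 7:2:1 ratios", {
  rec80 <- make_records(80)
  asg <- split_by_plant(rec80, seed = 1)
  expect_equal(as.integer(table(asg$split)[c("train", "validation", "test")]),
               c(56L, 16L, 8L))
  rec10 <- make_records(10)
  asg10 <- split_by_plant(rec10, seed = 1)
  expect_equal(as.integer(table(asg10$split)[c("train", "validation", "test")]),
               c(7L, 2L, 1L))
  expect_error(split_by_plant(rec10, ratios = c(0.5, 0.4, 0.2)),
               class = "ripecast_config_error")
})

test_that("plant split is deterministic, plant-disjoint, and temporally gapped", {
  rec <- make_records(20)
  a1 <- split_by_plant(rec, seed = 11)
  a2 <- split_by_plant(rec, seed = 11)
  expect_identical(tibble::as_tibble(a1), tibble::as_tibble(a2))
  expect_equal(anyDuplicated(a1$plant_id), 0L)
  lab <- apply_split(rec, a1)
  kept_train <- lab[lab$split != "test" & lab$keep, ]
  test_rec <- lab[lab$split == "test", ]
  expect_true(min(test_rec$timestamp) > max(kept_train$timestamp))
})

test_that("windowize builds stride-1 next-step datasets with S = n - T", {
  m <- matrix(seq_len(30 * 1), ncol = 1)
  w <- windowize(m, 24)
  expect_equal(dim(w$windows), c(6, 24, 1))
  m3 <- matrix(rnorm(120 * 3), ncol = 3)
  w3 <- windowize(m3, 24)
  expect_equal(dim(w3$windows), c(96, 24, 3))
  # every window strictly precedes its target
  for (s in c(1, 40, 96)) {
    expect_equal(w3$windows[s, , ], m3[s:(s + 23), ])
    expect_equal(w3$targets[s, ], m3[s + 24, ])
  }
  expect_error(windowize(matrix(rnorm(24), ncol = 1), 24),
               class = "ripecast_empty_dataset")
})

test_that("sensor CSV round-trips through ISO-8601 with empty cells as NA", {
  df <- make_series(1, miss_at = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sensor_csv(df, path)
  back <- read_sensor_csv(path)
  expect_s3_class(back$timestamp, "POSIXct")
  expect_true(is.na(back$temperature[5]))
  expect_equal(back$temperature[-5], df$temperature[-5], tolerance = 1e-9)
})
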