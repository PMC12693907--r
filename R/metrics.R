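# Evaluation metrics: coefficient of determination, mean absolute error,
# and root mean square error, plus tabular metric reports.

#' Coefficient of determination
#'
#' `R2 = 1 - sum((y' - y)^2) / sum((y - ybar)^2)`. Requires at least two
#' observations with nonzero variance in the truth.
#'
#' @param y_true,y_pred Numeric vectors of equal length.
#' @return Scalar R-squared (at most 1, unbounded below).
#' @export
r2 <- function(y_true, y_pred) {
  check_metric_input(y_true, y_pred, min_n = 2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) {
    abort("R2 undefined: zero variance in y_true.",
          class = "ripecast_undefined_r2")
  }
  1 - sum((y_pred - y_true)^2) / ss_tot
}

#' Mean absolute error
#'
#' @inheritParams r2
#' @return `mean(|y' - y|)`, in the target's units.
#' @export
mae <- function(y_true, y_pred) {
  check_metric_input(y_true, y_pred)
  mean(abs(y_pred - y_true))
}

#' Root mean square error
#'
#' @inheritParams r2
#' @return `sqrt(mean((y' - y)^2))`, in the target's units.
#' @export
rmse <- function(y_true, y_pred) {
  check_metric_input(y_true, y_pred)
  sqrt(mean((y_pred - y_true)^2))
}

check_metric_input <- function(y_true, y_pred, min_n = 1) {
  if (length(y_true) != length(y_pred)) {
    abort("y_true and y_pred must have equal length.")
  }
  if (length(y_true) < min_n) {
    abort(sprintf("need at least %d observations.", min_n))
  }
  invisible(TRUE)
}

#' Per-target metric report
#'
#' Computes R2, MAE and RMSE for each target column, in the layout of a
#' model-by-target-by-metric comparison table.
#'
#' @param truth,estimate Data frames (or matrices) with identical target
#'   columns.
#' @param model Label for the model column.
#' @param split Evaluation split label.
#' @return Tibble with `model`, `target`, `n`, `split`, `r2`, `mae`, `rmse`.
#' @export
metric_report <- function(truth, estimate, model = "model", split = "test") {
  truth <- as.data.frame(truth)
  estimate <- as.data.frame(estimate)
  purrr::map_dfr(names(truth), function(v) {
    r2v <- tryCatch(r2(truth[[v]], estimate[[v]]),
                    ripecast_undefined_r2 = function(e) NA_real_)
    tibble::tibble(model = model, target = v, n = nrow(truth), split = split,
                   r2 = r2v, mae = mae(truth[[v]], estimate[[v]]),
                   rmse = rmse(truth[[v]], estimate[[v]]))
  })
}

#' Write a metric report
#'
#' @param report A [metric_report()] tibble.
#' @param path Output path; `.json` or `.csv` by extension.
#' @export
write_metric_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  } else {
    write.csv(report, path, row.names = FALSE)
  }
  invisible(path)
}
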