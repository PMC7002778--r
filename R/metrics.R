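#' Chemometric evaluation metrics for a prediction set
#'
#' Computes the desirability indices conventional in NIR calibration:
#' `RMSE = sqrt(mean(e^2))`, `Bias = mean(e)`, `SE` (the SEP,
#' bias-corrected standard deviation of the errors,
#' `sqrt(sum((e - bias)^2) / (n - 1))`), `R2` (squared Pearson
#' correlation of measured and predicted) and `RPD = sd(y_true) / SE`.
#' An alternative `R2` as `1 - SSE/SST` is available via `r2_method`.
#'
#' @param y_true measured values.
#' @param y_pred predicted values, same length, `n >= 2`.
#' @param r2_method `"cor"` (default, squared correlation) or `"ss"`
#'   (`1 - SSE/SST`).
#' @param dataset_label optional label carried in the report.
#' @return Object of class `"metrics_report"`: one-row data.frame with
#'   columns `rmse`, `r2`, `rpd`, `bias`, `se`, `n`, `dataset_label`.
#' @export
compute_metrics <- function(y_true, y_pred, r2_method = c("cor", "ss"),
                            dataset_label = NA_character_) {
  r2_method <- match.arg(r2_method)
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  n <- length(y_true)
  if (length(y_pred) != n) stop_dim("y_true and y_pred lengths differ")
  if (n < 2) stop_dim("need at least 2 observations")
  if (sd(y_true) == 0)
    stop_dim("y_true has zero variance; R2 and RPD are undefined")
  e <- y_true - y_pred
  rmse <- sqrt(mean(e^2))
  bias <- mean(e)
  se <- sqrt(sum((e - bias)^2) / (n - 1))
  r2 <- if (sd(y_pred) == 0) {
    if (r2_method == "cor") 0 else 1 - sum(e^2) / sum((y_true - mean(y_true))^2)
  } else if (r2_method == "cor") {
    cor(y_true, y_pred)^2
  } else {
    1 - sum(e^2) / sum((y_true - mean(y_true))^2)
  }
  rpd <- if (se > 0) sd(y_true) / se else Inf
  out <- data.frame(rmse = rmse, r2 = r2, rpd = rpd, bias = bias, se = se,
                    n = n, dataset_label = dataset_label,
                    stringsAsFactors = FALSE)
  class(out) <- c("metrics_report", "data.frame")
  out
}

#' Read a calibration dataset from CSV
#'
#' Expects numeric predictor columns (by convention `x_1..x_m`) and a
#' response column; an optional logical/0-1 `is_outlier` column is carried
#' through as `truth_flags`.
#'
#' @param path CSV file path.
#' @param response response column name (default `"y"`).
#' @return a [regression_dataset()] with attribute `"truth_flags"` when
#'   an `is_outlier` column is present.
#' @export
read_dataset <- function(path, response = "y") {
  df <- read.csv(path, check.names = FALSE)
  if (!response %in% names(df))
    stop_dim("response column '", response, "' not found in ", path)
  flags <- NULL
  if ("is_outlier" %in% names(df)) {
    flags <- as.logical(df[["is_outlier"]])
    df[["is_outlier"]] <- NULL
  }
  y <- df[[response]]
  df[[response]] <- NULL
  x <- as.matrix(df)
  if (!is.numeric(x)) {
    bad <- which(!vapply(df, is.numeric, logical(1)))
    stop_dim("non-numeric predictor column(s): ",
             paste(names(df)[bad], collapse = ", "))
  }
  out <- regression_dataset(x, y)
  if (!is.null(flags)) attr(out, "truth_flags") <- flags
  out
}

#' Write a dataset (or prediction table) to CSV
#'
#' @param data a [regression_dataset()], `"simulated_dataset"`, or a
#'   data.frame of predictions.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  if (inherits(data, "simulated_dataset")) {
    df <- as.data.frame(data$x)
    df$y <- data$y
    df$is_outlier <- as.integer(data$truth_flags)
  } else if (inherits(data, "regression_dataset")) {
    df <- as.data.frame(data$x)
    if (is.null(colnames(data$x)))
      names(df) <- paste0("x_", seq_len(ncol(data$x)))
    df$y <- data$y
  } else df <- as.data.frame(data)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a prediction table to CSV
#'
#' @param path output path.
#' @param table data.frame with at least an identifier and `y_hat` column.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(path, table) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
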