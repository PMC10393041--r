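#' Forecast error metrics
#'
#' Mean absolute error, mean absolute percentage error (as a ratio, not a
#' percentage), and root mean square error over all (sample, step) pairs of
#' the test set. `RMSE >= MAE` always (Jensen's inequality).
#'
#' @param actual,predicted Numeric vectors/arrays of equal shape, mg/dL.
#' @param eps Optional guard added to `|actual|` in MAPE; `NULL` (default)
#'   errors on zero actuals instead.
#' @return Scalar metric value.
#' @export
mae <- function(actual, predicted) {
  check_metric_args(actual, predicted)
  mean(abs(actual - predicted))
}

#' @rdname mae
#' @export
mape <- function(actual, predicted, eps = NULL) {
  check_metric_args(actual, predicted)
  if (is.null(eps)) {
    if (any(actual == 0))
      stop("mape: zero actual value; pass eps to guard", call. = FALSE)
    eps <- 0
  }
  mean(abs(actual - predicted) / (abs(actual) + eps))
}

#' @rdname mae
#' @export
rmse <- function(actual, predicted) {
  check_metric_args(actual, predicted)
  sqrt(mean((actual - predicted)^2))
}

#' Pearson correlation between actuals and predictions
#'
#' @inheritParams mae
#' @return Product-moment correlation coefficient in `[-1, 1]`.
#' @export
pearson <- function(actual, predicted) {
  check_metric_args(actual, predicted)
  if (length(actual) < 2L)
    stop("pearson: need at least 2 points", call. = FALSE)
  if (sd(actual) == 0 || sd(predicted) == 0)
    stop("pearson: zero variance", call. = FALSE)
  cor(as.numeric(actual), as.numeric(predicted))
}

check_metric_args <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    stop("metrics: shape mismatch", call. = FALSE)
  if (length(actual) == 0L) stop("metrics: empty input", call. = FALSE)
  invisible(TRUE)
}

metric_row <- function(actual, predicted) {
  data.frame(MAE = mae(actual, predicted),
             MAPE = mape(actual, predicted),
             RMSE = rmse(actual, predicted),
             # degenerate (constant) predictions have no defined correlation
             PCC = tryCatch(pearson(actual, predicted),
                            error = function(e) NA_real_))
}
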