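#' Evaluate predictions against measurements
#'
#' The standard multivariate-calibration statistics: root-mean-square
#' error (RMSECV in cross-validation context, RMSEP on a prediction set),
#' Pearson correlation (Rcv / Rp — correlation, not R squared), mean
#' absolute error, and bias. Sign convention: `bias = mean(predicted -
#' measured)`, so over-prediction is positive.
#'
#' @param y_true Measured values (degrees Brix).
#' @param y_pred Predicted values, same length, `n >= 2`.
#' @param context `"calibration_cv"` or `"prediction"` (annotation only).
#' @return An `eval_report`: `rmse`, `r`, `mae`, `bias`, `n`, `context`.
#'   With a constant input vector the correlation is reported as `NA`
#'   with a warning; the error metrics remain valid.
#' @examples
#' evaluate(c(0, 0), c(3, 4))  # rmse = sqrt(12.5), mae = 3.5, bias = 3.5
#' @export
evaluate <- function(y_true, y_pred,
                     context = c("prediction", "calibration_cv")) {
  context <- match.arg(context)
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 2) stop("evaluate requires n >= 2")
  if (anyNA(y_true) || anyNA(y_pred) || any(!is.finite(c(y_true, y_pred)))) {
    stop("NaN or non-finite input")
  }
  e <- y_pred - y_true
  r <- if (stats::sd(y_true) == 0 || stats::sd(y_pred) == 0) {
    # error metrics are still well defined; only the correlation degenerates
    warning("constant input: correlation undefined, reported as NA")
    NA_real_
  } else stats::cor(y_true, y_pred)
  structure(list(
    rmse = sqrt(mean(e^2)),
    r = r,
    mae = mean(abs(e)),
    bias = mean(e),
    n = length(y_true),
    context = context
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> [%s] n=%d  RMSE=%.4g  R=%.4g  MAE=%.4g  Bias=%+.4g\n",
              x$context, x$n, x$rmse, x$r, x$mae, x$bias))
  invisible(x)
}
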