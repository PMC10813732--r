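# Classification and regression performance metrics.

#' Multiclass classification metrics from one-vs-rest counts
#'
#' For each class the window predictions are reduced to one-vs-rest
#' TP/FP/TN/FN counts, giving sensitivity `TP/(TP+FN)`, precision
#' `TP/(TP+FP)` and per-class F1.  Summary sensitivity and precision are
#' macro averages over classes present in the data (a class absent from
#' both truth and prediction is excluded); the summary F1 is the harmonic
#' mean of macro sensitivity and macro precision, and accuracy is the
#' overall fraction of correctly labeled windows.  Micro-averaged
#' sensitivity/precision (equal to accuracy in the single-label
#' multiclass case) are also reported.  A class that is never predicted
#' has precision 0; a class never true has sensitivity 0.
#'
#' @param true,pred Equal-length label vectors.
#' @param classes Class order for the per-class table (default
#'   [GESTURE_LEVELS] filtered to observed labels).
#' @return A `classification_report` list: `accuracy`, `sensitivity`,
#'   `precision`, `f1` (macro), `micro_sensitivity`, `micro_precision`,
#'   `per_class` data frame with counts, and `n`.
#' @export
classification_metrics <- function(true, pred, classes = NULL) {
  stopifnot(length(true) == length(pred))
  n <- length(true)
  if (n == 0L) stop("no predictions to score", call. = FALSE)
  observed <- unique(c(true, pred))
  if (is.null(classes))
    classes <- c(GESTURE_LEVELS[GESTURE_LEVELS %in% observed],
                 sort(setdiff(observed, GESTURE_LEVELS)))
  classes <- classes[classes %in% observed]
  per <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(true == cl & pred == cl)
    fp <- sum(true != cl & pred == cl)
    fn <- sum(true == cl & pred != cl)
    tn <- n - tp - fp - fn
    sens <- if (tp + fn > 0) tp / (tp + fn) else 0
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1 <- if (sens + prec > 0) 2 * sens * prec / (sens + prec) else 0
    data.frame(class = cl, tp = tp, fp = fp, tn = tn, fn = fn,
               sensitivity = sens, precision = prec, f1 = f1,
               stringsAsFactors = FALSE)
  }))
  macro_sens <- mean(per$sensitivity)
  macro_prec <- mean(per$precision)
  macro_f1 <- if (macro_sens + macro_prec > 0)
    2 * macro_sens * macro_prec / (macro_sens + macro_prec) else 0
  structure(list(
    accuracy = mean(true == pred),
    sensitivity = macro_sens,
    precision = macro_prec,
    f1 = macro_f1,
    micro_sensitivity = sum(per$tp) / sum(per$tp + per$fn),
    micro_precision = sum(per$tp) / sum(per$tp + per$fp),
    per_class = per,
    n = n
  ), class = "classification_report")
}

#' Regression metrics for fill-level and volume estimation
#'
#' MAPE `mean(|est - true| / true) * 100` (%), MAD `mean(|est - true|)`
#' (g), RMSE `sqrt(mean((est - true)^2))` (g) and, when `n >= 2`,
#' R-squared `1 - SS_res / SS_tot`.
#'
#' @param true True values in grams, all > 0 (required for MAPE).
#' @param est Estimated values, same length.
#' @return A `regression_report` list: `mape`, `mad`, `rmse`, `r2`, `n`.
#' @export
regression_metrics <- function(true, est) {
  stopifnot(length(true) == length(est))
  n <- length(true)
  if (n == 0L) stop("no predictions to score", call. = FALSE)
  if (any(true == 0)) stop("MAPE undefined for a zero true value",
                           call. = FALSE)
  err <- est - true
  sstot <- sum((true - mean(true))^2)
  r2 <- if (n >= 2 && sstot > 0) 1 - sum(err^2) / sstot else NA_real_
  structure(list(
    mape = mean(abs(err) / abs(true)) * 100,
    mad = mean(abs(err)),
    rmse = sqrt(mean(err^2)),
    r2 = r2,
    n = n
  ), class = "regression_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f | macro sens %.4f prec %.4f F1 %.4f | n = %d\n",
    x$accuracy, x$sensitivity, x$precision, x$f1, x$n))
  invisible(x)
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("MAPE %.2f%% | MAD %.2f g | RMSE %.2f g%s | n = %d\n",
              x$mape, x$mad, x$rmse,
              if (is.na(x$r2)) "" else sprintf(" | R2 %.3f", x$r2), x$n))
  invisible(x)
}
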