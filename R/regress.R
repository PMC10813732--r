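# Support vector regression layer shared by fill-level estimation and
# intake-volume estimation: linear or Gaussian kernel, features
# standardized with training-fold statistics, targets left in grams.

#' Fit a support vector regression model
#'
#' Epsilon-SVR with features standardized to the training set (constant
#' features pass through unscaled) and the target unstandardized, so
#' errors stay in grams.  The Gaussian kernel width defaults to
#' `1 / (n_features * mean feature variance)` after standardization.
#'
#' @param x Numeric feature matrix.
#' @param y Numeric target (grams).
#' @param kernel `"linear"` or `"gaussian"`.
#' @param cost Penalty parameter C (default 10).
#' @param epsilon Epsilon-tube half-width in grams (default 1).
#' @return An `svr_model` with a `predict` method.
#' @export
fit_svr <- function(x, y, kernel = c("linear", "gaussian"), cost = 10,
                    epsilon = 1) {
  kernel <- match.arg(kernel)
  if (nrow(x) < 2L) stop("need at least two training events", call. = FALSE)
  scaler <- fit_scaler(x)
  xs <- apply_scaler(x, scaler)
  v <- mean(apply(xs, 2, stats::var))
  gamma <- if (is.finite(v) && v > 0) 1 / (ncol(xs) * v) else 1 / ncol(xs)
  fit <- e1071::svm(xs, y, type = "eps-regression",
                    kernel = if (kernel == "linear") "linear" else "radial",
                    cost = cost, epsilon = epsilon, gamma = gamma,
                    scale = FALSE)
  structure(list(fit = fit, scaler = scaler, kernel = kernel),
            class = "svr_model")
}

#' @rdname fit_svr
#' @param object A fitted `svr_model`.
#' @param newdata Feature matrix with the training columns.
#' @param ... Unused.
#' @export
predict.svr_model <- function(object, newdata, ...) {
  as.numeric(stats::predict(object$fit,
                            apply_scaler(newdata, object$scaler)))
}

#' Train intake-volume model set (general or sip-size-dependent)
#'
#' `scope = "general"` fits one SVR on all training events;
#' `scope = "by_size"` fits one SVR per sip-size category present in the
#' training set, each on that category's events only.
#'
#' @param x Feature matrix (64 or 65 columns, see
#'   [extract_volume_features()]).
#' @param y True sip amounts in grams.
#' @param sizes Sip-size category per training event (used by
#'   `"by_size"`).
#' @param scope `"general"` or `"by_size"`.
#' @inheritParams fit_svr
#' @return A `volume_model_set`.
#' @export
train_volume_models <- function(x, y, sizes, scope = c("general", "by_size"),
                                kernel = "linear", cost = 10, epsilon = 1) {
  scope <- match.arg(scope)
  models <- if (scope == "general") {
    list(general = fit_svr(x, y, kernel, cost, epsilon))
  } else {
    cats <- unique(sizes)
    if (any(table(sizes) < 2))
      stop("a sip-size category has fewer than two training events",
           call. = FALSE)
    stats::setNames(lapply(cats, function(cat) {
      sel <- sizes == cat
      fit_svr(x[sel, , drop = FALSE], y[sel], kernel, cost, epsilon)
    }), cats)
  }
  structure(list(models = models, scope = scope, kernel = kernel),
            class = "volume_model_set")
}

#' Predict intake volume for a set of events
#'
#' General models ignore the category; sip-size-dependent models route
#' each event's features to the model of its (ground-truth) category.
#'
#' @param object A `volume_model_set` from [train_volume_models()].
#' @param newdata Feature matrix.
#' @param sizes Sip-size category per event (required for `"by_size"`).
#' @param ... Unused.
#' @return Numeric vector of estimated amounts in grams.
#' @export
predict.volume_model_set <- function(object, newdata, sizes = NULL, ...) {
  if (object$scope == "general")
    return(predict(object$models$general, newdata))
  if (is.null(sizes))
    stop("sip-size-dependent prediction needs a category per event",
         call. = FALSE)
  unknown <- setdiff(unique(sizes), names(object$models))
  if (length(unknown))
    stop(sprintf("no model for sip-size category '%s'", unknown[1]),
         call. = FALSE)
  out <- numeric(nrow(newdata))
  for (cat in unique(sizes)) {
    sel <- sizes == cat
    out[sel] <- predict(object$models[[cat]], newdata[sel, , drop = FALSE])
  }
  out
}
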