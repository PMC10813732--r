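# Gesture classification (RBF-kernel SVM), run-length label
# postprocessing, and mapping of window-label runs back to sample
# intervals.

fit_scaler <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1  # constant feature: leave as-is
  list(center = center, scale = scale)
}

apply_scaler <- function(x, scaler) {
  sweep(sweep(x, 2, scaler$center), 2, scaler$scale, "/")
}

# deterministic stratified subsample: every class keeps its share, picked
# at evenly spaced positions so results do not depend on RNG state
stratified_cap <- function(y, max_n) {
  n <- length(y)
  if (n <= max_n) return(seq_len(n))
  keep <- unlist(lapply(split(seq_len(n), y), function(ix) {
    k <- max(1L, floor(length(ix) / n * max_n))
    ix[unique(round(seq(1, length(ix), length.out = k)))]
  }), use.names = FALSE)
  sort(keep)
}

#' Train the RBF-kernel SVM gesture classifier
#'
#' Features are standardized with statistics of the training set only;
#' the kernel width defaults to `1 / (n_features * mean feature variance)`
#' computed after standardization (so effectively `1/96`).  Multiclass
#' handling is libsvm's one-vs-one vote with classes ordered
#' grasp < pre_sip < sip < post_sip < release.  Training sets larger than
#' `max_train` windows are reduced by a deterministic stratified subsample.
#'
#' @param x Numeric feature matrix (rows = windows, 96 columns).
#' @param y Window labels (character), at least two distinct classes.
#' @param cost SVM penalty parameter C (default 1).
#' @param max_train Cap on the number of training windows (default 2500).
#' @return A `gesture_classifier` with a [predict][predict.gesture_classifier]
#'   method returning character labels.
#' @export
train_gesture_classifier <- function(x, y, cost = 1, max_train = 2500) {
  lev <- GESTURE_LEVELS[GESTURE_LEVELS %in% unique(y)]
  if (length(lev) < 2L)
    stop("training set must contain at least two gesture classes",
         call. = FALSE)
  keep <- stratified_cap(factor(y, levels = lev), max_train)
  x <- x[keep, , drop = FALSE]
  y <- y[keep]
  scaler <- fit_scaler(x)
  xs <- apply_scaler(x, scaler)
  v <- mean(apply(xs, 2, stats::var))
  gamma <- if (is.finite(v) && v > 0) 1 / (ncol(xs) * v) else 1 / ncol(xs)
  fit <- e1071::svm(xs, factor(y, levels = lev), type = "C-classification",
                    kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  structure(list(fit = fit, scaler = scaler, levels = lev),
            class = "gesture_classifier")
}

#' @rdname train_gesture_classifier
#' @param object A fitted `gesture_classifier`.
#' @param newdata Feature matrix with the training columns.
#' @param ... Unused.
#' @export
predict.gesture_classifier <- function(object, newdata, ...) {
  as.character(stats::predict(object$fit, apply_scaler(newdata,
                                                       object$scaler)))
}

#' Correct isolated misclassified fragments in a label sequence
#'
#' Scans the predicted window-label sequence left to right and rewrites any
#' interior run of one fragment or two consecutive fragments whose
#' preceding and subsequent fragments carry the same label, replacing it
#' with the preceding fragment's label.  Corrections are applied in place
#' during the scan, so an early correction can enable a later one.
#' Fragments at the sequence boundaries (no neighbor on one side) are never
#' modified.  The sequence length is preserved and the operation is
#' idempotent.
#'
#' @param labels Character vector of predicted fragment labels.
#' @return Corrected character vector of the same length.
#' @export
#' @examples
#' postprocess_labels(c("g", "g", "o", "g", "g"))       # lone deviation
#' postprocess_labels(c("g", "g", "o", "o", "g", "g"))  # two-fragment run
postprocess_labels <- function(labels) {
  n <- length(labels)
  if (n == 0L) stop("postprocess_labels: empty sequence", call. = FALSE)
  x <- labels
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] != x[i - 1L]) {
      if (x[i] != x[i + 1L] && x[i - 1L] == x[i + 1L]) {
        x[i] <- x[i - 1L]                      # lone deviating fragment
      } else if (x[i] == x[i + 1L] && i + 2L <= n &&
                 x[i + 2L] == x[i - 1L]) {
        x[i] <- x[i + 1L] <- x[i - 1L]         # two-fragment deviation
      }
    }
    i <- i + 1L
  }
  x
}

#' Merge labeled windows into sample-level gesture segments
#'
#' Collapses consecutive equal-label windows into runs and converts window
#' indices to 1-based sample intervals using the window-midpoint
#' convention: the boundary between two adjacent runs falls halfway
#' between the midpoints of the two windows that straddle it; the first
#' run starts at the first window's first sample and the last run ends at
#' the last window's last sample.
#'
#' @param starts 1-based window start indices, ascending.
#' @param labels One label per window (after any postprocessing).
#' @param window_samples Window length in samples.
#' @return A data frame with one row per run: `label`, `start`, `end`
#'   (sample indices, inclusive).
#' @export
segments_from_labels <- function(starts, labels, window_samples) {
  stopifnot(length(starts) == length(labels), length(starts) > 0)
  r <- rle(labels)
  run_end_win <- cumsum(r$lengths)
  run_start_win <- c(1L, utils::head(run_end_win, -1) + 1L)
  n_runs <- length(r$values)
  # sample index of the cut after window j: midway between midpoints
  seg_start <- integer(n_runs)
  seg_end <- integer(n_runs)
  for (k in seq_len(n_runs)) {
    seg_start[k] <- if (k == 1L) starts[1L] else
      (floor((starts[run_end_win[k - 1L]] + starts[run_start_win[k]] +
                window_samples) / 2) + 1L)
    seg_end[k] <- if (k == n_runs)
      starts[length(starts)] + window_samples - 1L
    else
      floor((starts[run_end_win[k]] + starts[run_start_win[k + 1L]] +
               window_samples) / 2)
  }
  data.frame(label = r$values, start = as.integer(seg_start),
             end = as.integer(seg_end), stringsAsFactors = FALSE)
}

#' Locate the sip and motion intervals in a recognized segmentation
#'
#' Picks the longest `sip` run (earliest on ties) and extends it backwards
#' over an adjacent `pre_sip` run and forwards over an adjacent `post_sip`
#' run to delimit the motion span used for fill-level features.  Events
#' with no recognized sip run are flagged (`ok = FALSE`) and excluded from
#' volume estimation.
#'
#' @param segs Segment table from [segments_from_labels()].
#' @return A list: `ok`, and when `ok` is `TRUE` the 1-based inclusive
#'   sample intervals `sip` and `motion` (named `start`/`end` vectors).
#' @export
recognized_intervals <- function(segs) {
  sip_rows <- which(segs$label == "sip")
  if (length(sip_rows) == 0L) return(list(ok = FALSE))
  len <- segs$end[sip_rows] - segs$start[sip_rows]
  k <- sip_rows[which.max(len)]
  lo <- k
  while (lo > 1L && segs$label[lo - 1L] == "pre_sip") lo <- lo - 1L
  hi <- k
  while (hi < nrow(segs) && segs$label[hi + 1L] == "post_sip") hi <- hi + 1L
  list(ok = TRUE,
       sip = c(start = segs$start[k], end = segs$end[k]),
       motion = c(start = segs$start[lo], end = segs$end[hi]))
}
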