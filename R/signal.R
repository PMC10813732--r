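# Derived channels and sliding-window segmentation shared by both
# recognition arms.

# central finite difference scaled to units/s; one-sided at the ends
finite_diff <- function(x, fs) {
  n <- length(x)
  if (n == 1L) return(0)
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) * fs
  d[n] <- (x[n] - x[n - 1]) * fs
  if (n > 2L) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  d
}

#' Compute derived channels (angular acceleration, inclination)
#'
#' Angular acceleration is the central finite difference of the angular
#' velocity (one-sided at the series ends), in deg/s^2.  Inclination is the
#' per-axis angle between the acceleration vector and each sensor axis,
#' `acos(acc_i / |acc|)` in degrees, using the instantaneous acceleration
#' direction as the gravity proxy; a zero-norm acceleration maps to 90 deg
#' on every axis.
#'
#' @param s A `sensor_series` (see [synthesize_event()]).
#' @return A `derived_series`: the input plus `ang_acc` (n x 3, deg/s^2)
#'   and `incl` (n x 3, degrees in \[0, 180\]).
#' @export
derive_channels <- function(s) {
  n <- length(s$t)
  if (n == 0L) stop("derive_channels: empty series", call. = FALSE)
  fs <- s$sample_rate_hz
  ang_acc <- apply(s$gyr, 2, finite_diff, fs = fs)
  if (n == 1L) ang_acc <- matrix(ang_acc, 1, 3)
  norm <- sqrt(rowSums(s$acc^2))
  ratio <- s$acc / ifelse(norm == 0, Inf, norm)  # zero norm -> cos 0 -> 90 deg
  incl <- acos(pmin(pmax(ratio, -1), 1)) * 180 / pi
  colnames(ang_acc) <- colnames(incl) <- c("x", "y", "z")
  out <- s
  out$ang_acc <- ang_acc
  out$incl <- incl
  class(out) <- c("derived_series", "sensor_series")
  out
}

#' Sliding-window configuration
#'
#' @param window_samples Window length in samples; the study grid uses
#'   16, 24, 32, 40, 48 and 56.
#' @param overlap_pct Window overlap in percent; the grid uses 25, 50, 75
#'   and 87.5.  The implied step `window_samples * (1 - overlap_pct/100)`
#'   must be a positive integer.
#' @return An object of class `window_config` with the computed `step`.
#' @export
window_config <- function(window_samples = 32, overlap_pct = 50) {
  step <- window_samples * (1 - overlap_pct / 100)
  if (step <= 0 || abs(step - round(step)) > 1e-9)
    stop(sprintf(
      "window_samples %d with overlap %g%% gives non-integer step %g",
      window_samples, overlap_pct, step), call. = FALSE)
  structure(list(window_samples = as.integer(window_samples),
                 overlap_pct = overlap_pct, step = as.integer(round(step))),
            class = "window_config")
}

#' The full window-size / overlap study grid
#'
#' All 24 combinations of window sizes \{16, 24, 32, 40, 48, 56\} samples
#' and overlaps \{25, 50, 75, 87.5\}%.
#'
#' @return A data frame with columns `window_samples`, `overlap_pct`, `step`.
#' @export
window_grid <- function() {
  g <- expand.grid(window_samples = c(16L, 24L, 32L, 40L, 48L, 56L),
                   overlap_pct = c(25, 50, 75, 87.5))
  g$step <- mapply(function(w, o) window_config(w, o)$step,
                   g$window_samples, g$overlap_pct)
  g[order(g$window_samples, g$overlap_pct), c("window_samples",
                                              "overlap_pct", "step")]
}

# majority label of a window; ties go to the label occurring earliest
majority_label <- function(lab) {
  tab <- table(lab)
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) == 1L) return(winners)
  firsts <- vapply(winners, function(l) match(l, lab), integer(1))
  winners[which.min(firsts)]
}

#' Segment a series into sliding windows
#'
#' Windows start at 1-based sample indices `1, 1+step, 1+2*step, ...`;
#' a trailing partial window is discarded.  Each window's ground-truth
#' label is the majority of its per-sample labels (ties broken toward the
#' label whose run starts earlier in the window).
#'
#' @param d A `sensor_series` or `derived_series`.
#' @param wcfg A [window_config()].
#' @param range Optional `c(start, end)` 1-based sample interval to window
#'   (used to crop the container arm to its motion span); default the whole
#'   series.
#' @return A data frame with columns `start` (1-based sample index) and
#'   `true_label`, one row per window.
#' @export
slide_windows <- function(d, wcfg, range = NULL) {
  n <- length(d$t)
  lo <- 1L
  hi <- n
  if (!is.null(range)) {
    lo <- as.integer(range[[1]])
    hi <- as.integer(range[[2]])
  }
  w <- wcfg$window_samples
  if (hi - lo + 1L < w)
    stop("slide_windows: series shorter than one window", call. = FALSE)
  starts <- seq.int(lo, hi - w + 1L, by = wcfg$step)
  labs <- vapply(starts, function(s0) {
    majority_label(d$labels[s0:(s0 + w - 1L)])
  }, character(1))
  data.frame(start = starts, true_label = labs, stringsAsFactors = FALSE)
}
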