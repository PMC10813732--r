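# 96-dimensional window feature vector for gesture recognition:
# 8 statistics {mean, sd, variance, max, min, range, skewness, kurtosis}
# x 4 channel groups {acceleration, angular velocity, angular
# acceleration, inclination} x 3 axes.

GESTURE_STAT_NAMES <- c("mean", "sd", "var", "max", "min", "range",
                        "skew", "kurt")
GESTURE_CHANNEL_NAMES <- as.vector(t(outer(
  c("acc", "gyr", "ang_acc", "incl"), c("x", "y", "z"), paste, sep = "_")))

#' Names of the 96 gesture features, in extraction order
#'
#' Channel-major order: for each of the 12 channels (`acc_x` ... `incl_z`)
#' the 8 statistics mean, sd, var, max, min, range, skew, kurt.
#' @return Character vector of length 96.
#' @export
gesture_feature_names <- function() {
  as.vector(t(outer(GESTURE_CHANNEL_NAMES, GESTURE_STAT_NAMES,
                    paste, sep = "_")))
}

# stack the 12 derived channels into an n x 12 matrix in canonical order
channel_matrix <- function(d) {
  cbind(d$acc, d$gyr, d$ang_acc, d$incl)
}

# 8 statistics for every row of a windows-by-samples value matrix.
# Skewness and kurtosis are population central-moment ratios m3/m2^1.5 and
# m4/m2^2 (kurtosis non-excess, Gaussian ~ 3); zero-variance windows map
# both to 0 so constant channels never produce NaN.
window_stats <- function(M) {
  w <- ncol(M)
  mu <- rowMeans(M)
  Mc <- M - mu
  m2 <- rowMeans(Mc^2)
  sdv <- sqrt(rowSums(Mc^2) / (w - 1))
  cols <- lapply(seq_len(w), function(j) M[, j])
  mx <- do.call(pmax, cols)
  mn <- do.call(pmin, cols)
  m3 <- rowMeans(Mc^3)
  m4 <- rowMeans(Mc^4)
  skew <- ifelse(m2 > 0, m3 / m2^1.5, 0)
  kurt <- ifelse(m2 > 0, m4 / m2^2, 0)
  cbind(mean = mu, sd = sdv, var = sdv^2, max = mx, min = mn,
        range = mx - mn, skew = skew, kurt = kurt)
}

#' Gesture feature matrix for a set of windows
#'
#' Vectorized extraction of the 96 statistical features for every window of
#' one derived series.
#'
#' @param d A `derived_series` from [derive_channels()].
#' @param starts Integer vector of 1-based window start indices.
#' @param window_samples Window length in samples.
#' @return Numeric matrix, one row per window, columns named as
#'   [gesture_feature_names()].
#' @export
gesture_feature_matrix <- function(d, starts, window_samples) {
  E <- channel_matrix(d)
  idx <- outer(as.integer(starts), 0:(window_samples - 1L), `+`)
  out <- matrix(0, length(starts), 96)
  for (c_i in seq_len(12)) {
    ch <- E[, c_i]
    M <- matrix(ch[idx], nrow(idx), ncol(idx))
    out[, (c_i - 1L) * 8L + 1:8] <- window_stats(M)
  }
  colnames(out) <- gesture_feature_names()
  out
}

#' Extract the 96 gesture features of a single window
#'
#' @param start 1-based sample index where the window begins.
#' @param window_samples Window length in samples.
#' @param d A `derived_series`.
#' @return Named numeric vector of length 96.
#' @export
extract_gesture_features <- function(start, window_samples, d) {
  if (start < 1L || start + window_samples - 1L > length(d$t))
    stop("window exceeds series bounds", call. = FALSE)
  drop(gesture_feature_matrix(d, start, window_samples))
}
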