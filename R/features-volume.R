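# 64/65-dimensional feature vector for fill-level and intake-volume
# regression, extracted from the inclination channels of one gesture
# interval (the sip for volume; pre-sip..post-sip for fill level):
# duration, per-direction average / maximum / integral of inclination,
# per-direction counts of samples above fixed inclination thresholds
# (10..90 deg) and above fixed fractions of the interval maximum
# (10..90 %), optionally followed by the fill level in grams.

VOL_THRESHOLDS <- seq(10, 90, by = 10)

#' Names of the volume-regression features, in extraction order
#'
#' @param with_fill If `TRUE`, append `fill_level_g` (length 65),
#'   otherwise length 64.
#' @return Character vector of feature names.
#' @export
volume_feature_names <- function(with_fill = FALSE) {
  ax <- c("x", "y", "z")
  nm <- c("duration_s",
          paste0("incl_avg_", ax),
          paste0("incl_max_", ax),
          paste0("incl_int_", ax),
          as.vector(sapply(ax, function(a) paste0("cnt_deg_", a, "_",
                                                  VOL_THRESHOLDS))),
          as.vector(sapply(ax, function(a) paste0("cnt_pct_", a, "_",
                                                  VOL_THRESHOLDS))))
  if (with_fill) nm <- c(nm, "fill_level_g")
  nm
}

#' Extract volume-regression features from a gesture interval
#'
#' Duration is `n_samples / sample_rate`; the inclination integral uses
#' the trapezoidal rule over the interval timestamps, extended by half a
#' sampling interval at each end so that every sample owns a `1/fs` slot
#' and a constant signal integrates exactly to value x duration (deg s);
#' threshold
#' counts are raw sample counts of `inclination > k` degrees; normalized
#' counts use the interval's own per-direction maximum as denominator (a
#' zero maximum yields zero counts).
#'
#' @param interval `c(start, end)` 1-based inclusive sample interval.
#' @param d A `derived_series` from [derive_channels()].
#' @param fill_level_g Optional fill level in grams appended as the last
#'   feature.
#' @return Named numeric vector of length 64 (65 with `fill_level_g`).
#' @export
extract_volume_features <- function(interval, d, fill_level_g = NULL) {
  start <- as.integer(interval[[1]])
  end <- as.integer(interval[[2]])
  if (end < start) stop("empty gesture interval", call. = FALSE)
  incl <- d$incl[start:end, , drop = FALSE]
  ts <- d$t[start:end]
  n_s <- nrow(incl)
  f <- c(n_s / d$sample_rate_hz,
         colMeans(incl),
         apply(incl, 2, max),
         if (n_s > 1)
           apply(incl, 2, function(v)
             pracma::trapz(ts, v) + (v[1] + v[n_s]) / (2 * d$sample_rate_hz))
         else incl[1, ] / d$sample_rate_hz)
  cnt_deg <- as.vector(sapply(1:3, function(a)
    vapply(VOL_THRESHOLDS, function(k) sum(incl[, a] > k), numeric(1))))
  cnt_pct <- as.vector(sapply(1:3, function(a) {
    m <- max(incl[, a])
    if (m <= 0) return(rep(0, length(VOL_THRESHOLDS)))
    vapply(VOL_THRESHOLDS, function(p) sum(incl[, a] > p / 100 * m),
           numeric(1))
  }))
  f <- c(f, cnt_deg, cnt_pct)
  if (!is.null(fill_level_g)) f <- c(f, fill_level_g)
  names(f) <- volume_feature_names(with_fill = !is.null(fill_level_g))
  f
}
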