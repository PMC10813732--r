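# Shared fixtures: a small protocol for fast end-to-end tests and
# independent oracles used against the package implementations.

small_protocol <- function(seed = 42L, participants = 3L, reps = 2L,
                           fills = c(100, 250, 400)) {
  drink_protocol(n_participants = participants, fill_levels_g = fills,
                 repetitions = reps, seed = seed)
}

# memoized small dataset so several test files can share one generation
small_dataset <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 42L) {
    key <- as.character(seed)
    if (is.null(cache[[key]]))
      cache[[key]] <- generate_dataset(small_protocol(seed = seed))
    cache[[key]]
  }
})

# Independent fragment-correction oracle: walks runs left to right and
# rewrites any interior run of <= 2 fragments whose two flanking
# fragments agree, cascading corrections forward.
postprocess_oracle <- function(x) {
  n <- length(x)
  i <- 2L
  while (i < n) {
    if (x[i] != x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j - i + 1L <= 2L && j < n && x[j + 1L] == x[i - 1L])
        x[i:j] <- x[i - 1L]
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  x
}

# direct-summation classification metrics for one positive class
ovr_counts_oracle <- function(true, pred, cls) {
  tp <- 0; fp <- 0; tn <- 0; fn <- 0
  for (k in seq_along(true)) {
    if (true[k] == cls && pred[k] == cls) tp <- tp + 1
    else if (true[k] != cls && pred[k] == cls) fp <- fp + 1
    else if (true[k] == cls && pred[k] != cls) fn <- fn + 1
    else tn <- tn + 1
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

regression_oracle <- function(a, ahat) {
  n <- length(a)
  s_ape <- 0; s_ad <- 0; s_sq <- 0; s_tot <- 0
  abar <- sum(a) / n
  for (k in seq_len(n)) {
    s_ape <- s_ape + abs(ahat[k] - a[k]) / a[k]
    s_ad <- s_ad + abs(ahat[k] - a[k])
    s_sq <- s_sq + (ahat[k] - a[k])^2
    s_tot <- s_tot + (a[k] - abar)^2
  }
  list(mape = s_ape / n * 100, mad = s_ad / n, rmse = sqrt(s_sq / n),
       r2 = 1 - s_sq / s_tot)
}
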