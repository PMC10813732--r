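make_series <- function(acc, gyr, labels = NULL, fs = 128) {
  n <- nrow(acc)
  drinksense:::new_sensor_series(
    "wrist", (seq_len(n) - 1) / fs, acc, gyr,
    labels %||% rep("sip", n), fs)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("derived channels match closed forms", {
  n <- 256
  s <- make_series(matrix(rep(c(0, 0, 1), each = n), n, 3),
                   matrix(5, n, 3))
  d <- derive_channels(s)
  # derivative of a constant angular velocity is zero
  expect_equal(unname(d$ang_acc), matrix(0, n, 3))
  # gravity along +z: 90 deg on x and y, 0 on z
  expect_equal(unname(d$incl[1, ]), c(90, 90, 0), tolerance = 1e-10)

  # sinusoidal angular velocity: central difference tracks the analytic
  # derivative with O(dt^2) error
  fs <- 128
  t <- (0:511) / fs
  f0 <- 2
  gyr <- matrix(sin(2 * pi * f0 * t), ncol = 1)[, c(1, 1, 1)]
  d2 <- derive_channels(make_series(matrix(c(0, 0, 1), 512, 3,
                                           byrow = TRUE), gyr))
  analytic <- 2 * pi * f0 * cos(2 * pi * f0 * t)
  interior <- 2:511
  bound <- (2 * pi * f0)^3 / 6 * (1 / fs)^2  # |d3/dt3| * dt^2 / 6
  expect_lt(max(abs(d2$ang_acc[interior, 1] - analytic[interior])),
            bound * 1.01)

  expect_error(derive_channels(make_series(matrix(0, 0, 3),
                                           matrix(0, 0, 3))), "empty")
})

test_that("zero-norm acceleration maps to 90 degrees on every axis", {
  s <- make_series(matrix(0, 4, 3), matrix(0, 4, 3))
  expect_equal(unname(derive_channels(s)$incl),
               matrix(90, 4, 3))
})

test_that("inclination is invariant to uniform rescaling of acceleration", {
  set.seed(1)
  acc <- matrix(rnorm(60), 20, 3)
  d1 <- derive_channels(make_series(acc, matrix(0, 20, 3)))
  d2 <- derive_channels(make_series(3.7 * acc, matrix(0, 20, 3)))
  expect_equal(d1$incl, d2$incl, tolerance = 1e-12)
})

test_that("window starts and counts match brute-force enumeration on the full grid", {
  grid <- window_grid()
  expect_identical(nrow(grid), 24L)
  expect_identical(window_config(40, 25)$step, 30L)
  set.seed(33)
  lens <- sample(60:400, 5)
  for (g in seq_len(nrow(grid))) {
    w <- grid$window_samples[g]
    step <- grid$step[g]
    for (L in lens) {
      s <- make_series(matrix(rnorm(L * 3), L, 3), matrix(0, L, 3))
      win <- slide_windows(derive_channels(s),
                           window_config(w, grid$overlap_pct[g]))
      # oracle: enumerate every candidate start and keep full windows
      starts <- integer(0)
      pos <- 1L
      while (pos + w - 1L <= L) {
        starts <- c(starts, pos)
        pos <- pos + step
      }
      expect_identical(win$start, starts)
      expect_identical(nrow(win), as.integer(floor((L - w) / step) + 1))
    }
  }
})

test_that("window labels are the majority with earlier-run tie-break", {
  L <- 32
  labs <- c(rep("grasp", 16), rep("sip", 16))
  s <- make_series(matrix(0, L, 3), matrix(0, L, 3), labels = labs)
  win <- slide_windows(derive_channels(s), window_config(32, 50))
  expect_identical(win$true_label, "grasp")  # 16-16 tie, grasp starts first

  labs2 <- c(rep("grasp", 10), rep("sip", 22))
  s2 <- make_series(matrix(0, L, 3), matrix(0, L, 3), labels = labs2)
  expect_identical(slide_windows(derive_channels(s2),
                                 window_config(32, 50))$true_label, "sip")

  expect_error(slide_windows(derive_channels(s), window_config(56, 25)),
               "shorter")
})
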