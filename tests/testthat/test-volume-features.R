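const_incl_series <- function(theta_deg, n, fs = 128) {
  th <- theta_deg * pi / 180
  drinksense:::new_sensor_series(
    "container", (0:(n - 1)) / fs,
    matrix(rep(c(0, sin(th), cos(th)), each = n), n, 3),
    matrix(0, n, 3), rep("sip", n), fs)
}

test_that("feature vector length is 64 without and 65 with the fill level", {
  d <- derive_channels(const_incl_series(30, 64))
  expect_length(extract_volume_features(c(1, 64), d), 64)
  expect_length(extract_volume_features(c(1, 64), d, fill_level_g = 250), 65)
  expect_identical(names(extract_volume_features(c(1, 64), d, 250))[65],
                   "fill_level_g")
})

test_that("a constant 45-degree inclination over 1 s gives the closed-form features", {
  d <- derive_channels(const_incl_series(45, 128))
  f <- extract_volume_features(c(1, 128), d)
  expect_equal(unname(f["duration_s"]), 1)
  expect_equal(unname(f["incl_avg_z"]), 45, tolerance = 1e-10)
  expect_equal(unname(f["incl_max_z"]), 45, tolerance = 1e-10)
  expect_equal(unname(f["incl_int_z"]), 45, tolerance = 1e-8)
  expect_equal(unname(f["cnt_deg_z_40"]), 128)
  expect_equal(unname(f["cnt_deg_z_50"]), 0)
  expect_error(extract_volume_features(c(10, 5), d), "empty")
})

test_that("threshold counts on a linear ramp match a per-sample brute-force counter", {
  n <- 200
  fs <- 128
  theta <- seq(0, 90, length.out = n)
  th <- theta * pi / 180
  s <- drinksense:::new_sensor_series(
    "container", (0:(n - 1)) / fs, cbind(0, sin(th), cos(th)),
    matrix(0, n, 3), rep("sip", n), fs)
  d <- derive_channels(s)
  f <- extract_volume_features(c(1, n), d)
  incl_z <- d$incl[, 3]
  for (k in seq(10, 90, by = 10)) {
    expect_equal(unname(f[paste0("cnt_deg_z_", k)]),
                 sum(incl_z > k))
    expect_equal(unname(f[paste0("cnt_pct_z_", k)]),
                 sum(incl_z > k / 100 * max(incl_z)))
  }
})

test_that("threshold counts are non-increasing in k and p, and avg <= max", {
  ds <- small_dataset()
  for (ev in ds[1:8]) {
    d <- derive_channels(ev$container)
    f <- extract_volume_features(drinksense:::true_sip_interval(ev), d,
                                 ev$fill_level_g)
    for (a in c("x", "y", "z")) {
      expect_true(all(diff(f[paste0("cnt_deg_", a, "_",
                                    seq(10, 90, 10))]) <= 0))
      expect_true(all(diff(f[paste0("cnt_pct_", a, "_",
                                    seq(10, 90, 10))]) <= 0))
      expect_lte(f[[paste0("incl_avg_", a)]], f[[paste0("incl_max_", a)]])
      expect_gte(f[[paste0("incl_int_", a)]], 0)
    }
    expect_gt(f[["duration_s"]], 0)
  }
})

test_that("a zero maximum inclination yields zero normalized counts", {
  n <- 64
  s <- drinksense:::new_sensor_series(
    "container", (0:(n - 1)) / 128,
    matrix(rep(c(0, 0, 1), each = n), n, 3),
    matrix(0, n, 3), rep("sip", n), 128)
  f <- extract_volume_features(c(1, n), derive_channels(s))
  expect_true(all(f[paste0("cnt_pct_z_", seq(10, 90, 10))] == 0))
})
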