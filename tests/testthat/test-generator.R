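test_that("the event grid factorizes exactly and has no duplicate cells", {
  ds <- small_dataset()
  cfg <- attr(ds, "protocol")
  expect_length(ds, cfg$n_participants * length(cfg$fill_levels_g) *
                  3 * cfg$repetitions)
  keys <- vapply(ds, function(e) e$event_id, character(1))
  expect_false(anyDuplicated(keys) > 0)

  cfg1 <- drink_protocol(n_participants = 1, fill_levels_g = 200,
                         sip_sizes = "medium", repetitions = 1, seed = 5)
  expect_length(generate_dataset(cfg1), 1L)
})

test_that("identical seeds reproduce identical events", {
  cfg <- small_protocol(seed = 9L, participants = 1L, reps = 1L,
                        fills = 200)
  expect_identical(generate_dataset(cfg), generate_dataset(cfg))

  set.seed(123)
  prof <- drinksense:::participant_profiles(1)[[1]]
  set.seed(77)
  e1 <- synthesize_event(prof, 200, "medium", sip_size_model(),
                         drink_protocol())
  set.seed(77)
  e2 <- synthesize_event(prof, 200, "medium", sip_size_model(),
                         drink_protocol())
  expect_identical(e1, e2)
})

test_that("every event carries the five ordered nonempty phases on a common clock", {
  for (ev in small_dataset()[seq(1, 54, by = 7)]) {
    expect_identical(ev$phases$phase, GESTURE_LEVELS)
    expect_true(all(ev$phases$end >= ev$phases$start))
    expect_identical(ev$phases$start[-1], head(ev$phases$end, -1) + 1L)
    expect_identical(rle(ev$wrist$labels)$values, GESTURE_LEVELS)
    expect_identical(ev$wrist$labels, ev$container$labels)
    expect_identical(ev$wrist$t, ev$container$t)
    expect_equal(diff(ev$wrist$t),
                 rep(1 / 128, length(ev$wrist$t) - 1))
    expect_true(ev$true_amount_g > 0 &&
                  ev$true_amount_g <= ev$fill_level_g)
  }
})

test_that("generated channels never exceed the sensor ranges", {
  for (ev in small_dataset()) {
    for (arm in c("wrist", "container")) {
      expect_true(all(abs(ev[[arm]]$acc) <= 16))
      expect_true(all(abs(ev[[arm]]$gyr) <= 2000))
    }
  }
})

test_that("the container is stationary outside pre-sip..post-sip", {
  for (ev in small_dataset()[1:6]) {
    rest <- ev$container$labels %in% c("grasp", "release")
    acc <- ev$container$acc[rest, ]
    expect_equal(colMeans(acc), c(x = 0, y = 0, z = 1), tolerance = 0.02)
    expect_lt(max(abs(ev$container$gyr[rest, ])), 10)
    # wrist sensor noise exceeds container noise (compare rest phases,
    # where both tilt trajectories are constant)
    expect_gt(stats::sd(ev$wrist$acc[rest, 2]),
              2 * stats::sd(ev$container$acc[rest, 2]))
  }
})

test_that("sip amounts match the configured truncated-normal moments", {
  model <- sip_size_model()
  set.seed(101)
  for (cat in names(model$mean_g)) {
    draws <- draw_sip_amount(500, cat, model, cap_g = Inf)
    # oracle: moments of the same truncation from a large direct sample
    raw <- stats::rnorm(2e5, model$mean_g[[cat]], model$sd_g[[cat]])
    raw <- raw[raw >= model$floor_g]
    se <- stats::sd(raw) / sqrt(500)
    expect_lt(abs(mean(draws) - mean(raw)), 2 * se)
    expect_true(all(draws >= model$floor_g))
  }
})

test_that("sip duration grows with the drawn amount", {
  model <- sip_size_model()
  set.seed(55)
  prof <- drinksense:::participant_profiles(1)[[1]]
  amounts <- seq(5, 50, by = 5)
  durs <- vapply(amounts, function(a)
    drinksense:::sip_duration_s(a, "medium", model, prof$speed), numeric(1))
  expect_true(all(diff(durs) > 0))
})

test_that("peak sip tilt is larger at low fill than at high fill", {
  set.seed(7)
  model <- sip_size_model()
  cfg <- drink_protocol()
  prof <- drinksense:::participant_profiles(1)[[1]]
  peak_tilt <- function(fill) {
    ev <- synthesize_event(prof, fill, "medium", model, cfg)
    d <- derive_channels(ev$container)
    iv <- drinksense:::true_sip_interval(ev)
    max(d$incl[iv[1]:iv[2], 3])
  }
  lo <- replicate(200, peak_tilt(100))
  hi <- replicate(200, peak_tilt(400))
  expect_gt(mean(lo), mean(hi))
})
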