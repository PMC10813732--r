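test_that("LOSO folds are exhaustive, disjoint and participant-pure", {
  ds <- small_dataset()
  folds <- loso_folds(ds)
  expect_length(folds, 3)
  all_test <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_identical(all_test, seq_along(ds))  # each event tested once
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    test_p <- unique(vapply(ds[f$test], function(e) e$participant,
                            character(1)))
    expect_identical(test_p, f$participant)
    expect_false(f$participant %in%
                   vapply(ds[f$train], function(e) e$participant,
                          character(1)))
  }
})

test_that("gesture LOSO beats the majority-class baseline on both arms", {
  ds <- small_dataset()
  for (arm in c("wrist", "container")) {
    res <- run_gesture_loso(ds, arm, window_config(32, 50))
    baseline <- max(table(res$windows$true_label)) / nrow(res$windows)
    expect_gt(res$report_raw$accuracy, baseline)
    expect_true(all(res$windows$pred %in% GESTURE_LEVELS))
    if (arm == "container")
      expect_true(all(res$windows$true_label %in% CONTAINER_LEVELS))
  }
})

test_that("postprocessing repairs isolated label flips in ground-truth sequences", {
  ds <- small_dataset()
  set.seed(31)
  n_correct_before <- 0; n_correct_after <- 0; n_total <- 0
  for (ev in ds) {
    d <- ev$wrist
    win <- slide_windows(derive_channels(d), window_config(32, 50))
    truth <- win$true_label
    noisy <- truth
    # ~5% isolated flips, kept >= 3 apart so each stays a lone deviation
    cand <- seq(3, length(truth) - 2, by = 3)
    flip <- sample(cand, min(length(cand),
                             max(1, round(0.05 * length(truth)))))
    for (i in flip)
      noisy[i] <- sample(setdiff(GESTURE_LEVELS, noisy[i]), 1)
    fixed <- postprocess_labels(noisy)
    n_total <- n_total + length(truth)
    n_correct_before <- n_correct_before + sum(noisy == truth)
    n_correct_after <- n_correct_after + sum(fixed == truth)
  }
  expect_gt(n_correct_after, n_correct_before)
  # most injected flips are repaired (those at true phase boundaries
  # are not flanked by agreeing neighbors and legitimately remain)
  expect_gt(n_correct_after - n_correct_before,
            0.5 * (n_total - n_correct_before))
})

test_that("fill-level regression from container motion explains held-out variance", {
  ds <- small_dataset()
  r <- estimate_fill_levels(ds, "container", "linear")
  expect_gt(r$report$r2, 0)  # better than predicting the mean fill
  expect_length(r$estimates, length(ds))
  expect_true(all(is.finite(r$estimates)))
})

test_that("the window grid study tabulates cells and selects the best by postprocessed accuracy", {
  ds <- small_dataset()
  sub <- data.frame(window_samples = c(32L, 32L), overlap_pct = c(25, 50))
  g <- run_window_grid(ds, "wrist", grid = sub)
  expect_identical(nrow(g$grid), 2L)
  expect_true(all(g$grid$accuracy >= 0 & g$grid$accuracy <= 1))
  expect_equal(g$best$accuracy_post, max(g$grid$accuracy_post))

  path <- withr::local_tempfile(fileext = ".csv")
  write_grid_csv(g, path)
  expect_identical(nrow(utils::read.csv(path)), 1L)  # one window size row
})

test_that("postprocessing helps the noisier wrist arm at least as much as the container arm across seeds", {
  wins <- 0L
  for (seed in 301:305) {
    ds <- generate_dataset(small_protocol(seed = seed))
    imp <- vapply(c("wrist", "container"), function(arm) {
      r <- run_gesture_loso(ds, arm, window_config(32, 50))
      r$report_post$accuracy - r$report_raw$accuracy
    }, numeric(1))
    wins <- wins + (imp[["wrist"]] >= imp[["container"]])
  }
  expect_gte(wins, 3L)
})

test_that("the full study returns a coherent report bundle on a small protocol", {
  st <- run_full_study(cfg = small_protocol(seed = 61L))
  expect_s3_class(st, "drink_study")
  expect_identical(st$n_events, 54L)
  expect_identical(nrow(st$combination), 8L)
  expect_setequal(unique(st$combination$fill_source),
                  c("none", "true", "estimated"))
  expect_true(all(is.finite(st$combination$mad)))
  expect_true(all(st$volume$rmse >= st$volume$mad))  # RMSE >= MAD always
  expect_true(all(st$unrecognized >= 0))
  # every event got a finite prediction in the true-segment volume study
  expect_true(all(st$volume$n[st$volume$category == "all"] == 54))

  out <- withr::local_tempdir()
  save_study(st, out)
  expect_true(file.exists(file.path(out, "summary.json")))
  expect_identical(nrow(utils::read.csv(file.path(out,
                                                  "combination.csv"))), 8L)
  preds <- utils::read.csv(file.path(out, "predictions.csv"))
  expect_setequal(names(preds), c("event_id", "arm", "data_source",
                                  "fill_source", "model_scope", "kernel",
                                  "true_g", "est_g"))
  expect_true(all(is.finite(preds$est_g)))
})
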