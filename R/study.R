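# Leave-one-subject-out evaluation: gesture-recognition LOSO, the
# window/overlap grid study, fill-level and intake-volume regression
# studies, and the end-to-end combination study.

#' Leave-one-subject-out fold assignment
#'
#' One fold per participant; the fold's test set is all of that
#' participant's events and its training set is everyone else's.
#'
#' @param dataset A `drink_dataset`.
#' @return List of folds, each `list(participant, train, test)` with event
#'   indices.
#' @export
loso_folds <- function(dataset) {
  participants <- vapply(dataset, function(e) e$participant, character(1))
  lapply(unique(participants), function(p) {
    list(participant = p,
         train = which(participants != p),
         test = which(participants == p))
  })
}

# derived series for one arm of every event
derive_arm <- function(dataset, arm) {
  lapply(dataset, function(e) derive_channels(e[[arm]]))
}

# window features + metadata for one arm at one window config; the
# container arm is windowed only over its pre-sip..post-sip motion span
# (its signal outside that span is a stationary cup)
build_arm_windows <- function(dataset, derived, arm, wcfg) {
  per_event <- lapply(seq_along(dataset), function(i) {
    ev <- dataset[[i]]
    rng <- if (arm == "container") true_motion_interval(ev) else NULL
    win <- slide_windows(derived[[i]], wcfg, range = rng)
    feats <- gesture_feature_matrix(derived[[i]], win$start,
                                    wcfg$window_samples)
    list(meta = data.frame(event = i, participant = ev$participant,
                           start = win$start, true_label = win$true_label,
                           stringsAsFactors = FALSE),
         feats = feats)
  })
  list(X = do.call(rbind, lapply(per_event, `[[`, "feats")),
       meta = do.call(rbind, lapply(per_event, `[[`, "meta")))
}

# LOSO window predictions for one arm's feature table
gesture_loso <- function(X, meta, cost = 1, max_train = 2500) {
  pred <- character(nrow(meta))
  for (p in unique(meta$participant)) {
    test <- meta$participant == p
    clf <- train_gesture_classifier(X[!test, , drop = FALSE],
                                    meta$true_label[!test],
                                    cost = cost, max_train = max_train)
    pred[test] <- predict(clf, X[test, , drop = FALSE])
  }
  pred
}

# apply the fragment-correction rule within each event's window sequence
postprocess_by_event <- function(meta, pred) {
  out <- pred
  for (i in unique(meta$event)) {
    sel <- which(meta$event == i)
    out[sel] <- postprocess_labels(pred[sel])
  }
  out
}

#' Gesture-recognition LOSO for one arm and window configuration
#'
#' Windows the arm's derived series, runs leave-one-subject-out SVM
#' classification and the fragment postprocessing rule, and scores both
#' raw and postprocessed window labels.
#'
#' @param dataset A `drink_dataset`.
#' @param arm `"wrist"` or `"container"`.
#' @param wcfg A [window_config()].
#' @param derived Optional precomputed [derive_channels()] list for the arm
#'   (recomputed if omitted).
#' @param cost,max_train Passed to [train_gesture_classifier()].
#' @return A list: `windows` (metadata plus `pred` and `pred_post`
#'   columns), `report_raw`, `report_post` ([classification_metrics()]),
#'   `arm`, `wcfg`.
#' @export
run_gesture_loso <- function(dataset, arm = c("wrist", "container"),
                             wcfg = window_config(32, 50), derived = NULL,
                             cost = 1, max_train = 2500) {
  arm <- match.arg(arm)
  if (is.null(derived)) derived <- derive_arm(dataset, arm)
  aw <- build_arm_windows(dataset, derived, arm, wcfg)
  pred <- gesture_loso(aw$X, aw$meta, cost = cost, max_train = max_train)
  pred_post <- postprocess_by_event(aw$meta, pred)
  meta <- aw$meta
  meta$pred <- pred
  meta$pred_post <- pred_post
  list(windows = meta,
       report_raw = classification_metrics(meta$true_label, pred),
       report_post = classification_metrics(meta$true_label, pred_post),
       arm = arm, wcfg = wcfg)
}

#' Window-size / overlap grid study
#'
#' Runs [run_gesture_loso()] over all 24 combinations of window size and
#' overlap for one arm and tabulates accuracy, macro sensitivity,
#' precision and F1 with and without postprocessing.  The best cell is
#' the highest postprocessed accuracy, ties broken toward the smaller
#' window, then the smaller overlap.
#'
#' @inheritParams run_gesture_loso
#' @param grid Data frame of cells (default [window_grid()]).
#' @return A list: `grid` (one row per cell with metrics) and `best`
#'   (the selected row).
#' @export
run_window_grid <- function(dataset, arm = c("wrist", "container"),
                            grid = window_grid(), cost = 1,
                            max_train = 2500) {
  arm <- match.arg(arm)
  derived <- derive_arm(dataset, arm)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    wcfg <- window_config(grid$window_samples[g], grid$overlap_pct[g])
    res <- run_gesture_loso(dataset, arm, wcfg, derived = derived,
                            cost = cost, max_train = max_train)
    data.frame(window_samples = wcfg$window_samples,
               overlap_pct = wcfg$overlap_pct,
               accuracy = res$report_raw$accuracy,
               f1 = res$report_raw$f1,
               accuracy_post = res$report_post$accuracy,
               f1_post = res$report_post$f1)
  })
  tab <- do.call(rbind, rows)
  ord <- order(-tab$accuracy_post, tab$window_samples, tab$overlap_pct)
  list(grid = tab, best = tab[ord[1], ], arm = arm)
}

# recognized sip/motion sample intervals per event from postprocessed
# window labels
recognized_by_event <- function(meta, wcfg) {
  lapply(sort(unique(meta$event)), function(i) {
    sel <- meta$event == i
    segs <- segments_from_labels(meta$start[sel], meta$pred_post[sel],
                                 wcfg$window_samples)
    recognized_intervals(segs)
  })
}

# volume/fill feature table over a list of per-event intervals; NULL
# entries (unrecognized events) yield NA rows
interval_features <- function(derived, intervals, fills = NULL) {
  with_fill <- !is.null(fills)
  p <- length(volume_feature_names(with_fill))
  X <- matrix(NA_real_, length(intervals), p)
  for (i in seq_along(intervals)) {
    iv <- intervals[[i]]
    if (is.null(iv)) next
    X[i, ] <- extract_volume_features(iv, derived[[i]],
                                      if (with_fill) fills[i] else NULL)
  }
  colnames(X) <- volume_feature_names(with_fill)
  X
}

#' Leave-one-subject-out fill-level estimation for one arm
#'
#' Extracts the 64 duration/inclination features over each event's
#' pre-sip..post-sip span (true phase boundaries by default; pass
#' recognized intervals for the end-to-end condition) and predicts the
#' fill level with an SVR trained on the other participants' events.
#'
#' @param dataset A `drink_dataset`.
#' @param arm `"wrist"` or `"container"`.
#' @param kernel `"linear"` or `"gaussian"`.
#' @param intervals Optional list of per-event `c(start, end)` sample
#'   intervals (`NULL` entries skip the event); defaults to the annotated
#'   motion spans.
#' @param derived Optional precomputed [derive_channels()] list.
#' @return A list: `estimates` (grams, `NA` for skipped events) and
#'   `report` ([regression_metrics()] over the estimated events).
#' @export
estimate_fill_levels <- function(dataset, arm = c("wrist", "container"),
                                 kernel = c("linear", "gaussian"),
                                 intervals = NULL, derived = NULL) {
  arm <- match.arg(arm)
  kernel <- match.arg(kernel)
  if (is.null(derived)) derived <- derive_arm(dataset, arm)
  if (is.null(intervals)) intervals <- lapply(dataset, true_motion_interval)
  X <- interval_features(derived, intervals)
  fills <- vapply(dataset, function(e) e$fill_level_g, numeric(1))
  parts <- vapply(dataset, function(e) e$participant, character(1))
  est <- svr_loso(X, fills, parts, kernel)
  keep <- !is.na(est)
  list(estimates = est, report = regression_metrics(fills[keep], est[keep]))
}

# generic LOSO regression driver; rows with NA features are skipped
svr_loso <- function(X, y, participants, kernel, sizes = NULL,
                     scope = "general", cost = 10, epsilon = 1) {
  ok <- stats::complete.cases(X)
  est <- rep(NA_real_, length(y))
  for (p in unique(participants)) {
    test <- ok & participants == p
    if (!any(test)) next
    train <- ok & participants != p
    ms <- train_volume_models(X[train, , drop = FALSE], y[train],
                              sizes[train], scope = scope, kernel = kernel,
                              cost = cost, epsilon = epsilon)
    est[test] <- predict(ms, X[test, , drop = FALSE],
                         sizes = sizes[test])
  }
  est
}

#' Run the full assessment study on one synthetic dataset
#'
#' End-to-end pipeline at the per-arm reference window configurations:
#' gesture-recognition LOSO with postprocessing for both arms,
#' recognized-segment extraction, fill-level estimation (linear and
#' Gaussian SVR, recognized pre-sip..post-sip spans), the four
#' feature/model combinations for intake volume on true sip segments
#' (general vs sip-size-dependent, with and without fill level, both
#' kernels), and the combination study crossing true/recognized segments
#' with and without fill-level features.
#'
#' @param cfg A [drink_protocol()]; `cfg$seed` drives all randomness.
#' @param sip_model A [sip_size_model()].
#' @param wrist_wcfg,container_wcfg Per-arm [window_config()] (defaults:
#'   32 samples at 50% for the wrist, 40 samples at 25% for the
#'   container).
#' @param max_train Training-window cap for the gesture SVM.
#' @param dataset Optional pre-generated (or deserialized) `drink_dataset`;
#'   when supplied, `cfg` and `sip_model` are taken from its attributes.
#' @return A `drink_study` list: `recognition` (per arm), `fill_level`
#'   (per arm x kernel [regression_metrics()] plus linear-kernel
#'   estimates), `volume` (metric table over scope x kernel x fill,
#'   overall and per category), `combination` (8-row table), counts of
#'   events without a recognized sip, and the generating config.
#' @export
run_full_study <- function(cfg = drink_protocol(),
                           sip_model = sip_size_model(),
                           wrist_wcfg = window_config(32, 50),
                           container_wcfg = window_config(40, 25),
                           max_train = 2500, dataset = NULL) {
  if (is.null(dataset)) {
    dataset <- generate_dataset(cfg, sip_model)
  } else {
    cfg <- attr(dataset, "protocol")
  }
  participants <- vapply(dataset, function(e) e$participant, character(1))
  fills <- vapply(dataset, function(e) e$fill_level_g, numeric(1))
  sizes <- vapply(dataset, function(e) e$sip_size, character(1))
  amounts <- vapply(dataset, function(e) e$true_amount_g, numeric(1))
  event_ids <- vapply(dataset, function(e) e$event_id, character(1))

  arms <- c("wrist", "container")
  wcfgs <- list(wrist = wrist_wcfg, container = container_wcfg)
  recognition <- list()
  fill_level <- list()
  volume_rows <- list()
  combo_rows <- list()
  pred_rows <- list()
  unrecognized <- c(wrist = 0L, container = 0L)

  for (arm in arms) {
    derived <- derive_arm(dataset, arm)
    rec <- run_gesture_loso(dataset, arm, wcfgs[[arm]], derived = derived,
                            max_train = max_train)
    recognition[[arm]] <- rec

    rec_iv <- recognized_by_event(rec$windows, wcfgs[[arm]])
    sip_rec <- lapply(rec_iv, function(r) if (r$ok) r$sip else NULL)
    motion_rec <- lapply(rec_iv, function(r) if (r$ok) r$motion else NULL)
    unrecognized[[arm]] <- sum(vapply(rec_iv, function(r) !r$ok, logical(1)))

    # fill-level estimation on recognized pre-sip..post-sip spans
    fl <- list()
    for (kern in c("linear", "gaussian")) {
      r <- estimate_fill_levels(dataset, arm, kern, intervals = motion_rec,
                                derived = derived)
      fl[[kern]] <- r$report
      if (kern == "linear") fl$estimates <- r$estimates
    }
    fill_level[[arm]] <- fl

    # volume estimation on true sip segments, true fill levels
    sip_true <- lapply(dataset, true_sip_interval)
    X64 <- interval_features(derived, sip_true)
    X65 <- interval_features(derived, sip_true, fills = fills)
    for (scope in c("general", "by_size")) {
      for (kern in c("linear", "gaussian")) {
        for (wf in c(FALSE, TRUE)) {
          est <- svr_loso(if (wf) X65 else X64, amounts, participants,
                          kern, sizes = sizes, scope = scope)
          rep_all <- regression_metrics(amounts, est)
          volume_rows[[length(volume_rows) + 1L]] <- data.frame(
            arm = arm, scope = scope, kernel = kern, with_fill = wf,
            category = "all", mape = rep_all$mape, mad = rep_all$mad,
            rmse = rep_all$rmse, n = rep_all$n)
          for (cat in unique(sizes)) {
            sel <- sizes == cat
            rc <- regression_metrics(amounts[sel], est[sel])
            volume_rows[[length(volume_rows) + 1L]] <- data.frame(
              arm = arm, scope = scope, kernel = kern, with_fill = wf,
              category = cat, mape = rc$mape, mad = rc$mad,
              rmse = rc$rmse, n = rc$n)
          }
        }
      }
    }

    # combination study: {true, recognized} segments x {no fill, fill},
    # general linear SVR; recognized columns use the estimated fill level
    Xr64 <- interval_features(derived, sip_rec)
    est_fill <- fill_level[[arm]]$estimates
    for (src in c("true", "recognized")) {
      for (wf in c(FALSE, TRUE)) {
        Xc <- if (src == "true") {
          if (wf) X65 else X64
        } else {
          if (wf) {
            Xr <- cbind(Xr64, fill_level_g = est_fill)
            colnames(Xr) <- volume_feature_names(TRUE)
            Xr
          } else Xr64
        }
        est <- svr_loso(Xc, amounts, participants, "linear")
        keep <- !is.na(est)
        rp <- regression_metrics(amounts[keep], est[keep])
        fill_src <- if (!wf) "none" else if (src == "true") "true"
                    else "estimated"
        combo_rows[[length(combo_rows) + 1L]] <- data.frame(
          arm = arm, data_source = src, fill_source = fill_src,
          mape = rp$mape, mad = rp$mad, rmse = rp$rmse, n = rp$n)
        pred_rows[[length(pred_rows) + 1L]] <- data.frame(
          event_id = event_ids[keep], arm = arm, data_source = src,
          fill_source = fill_src, model_scope = "general",
          kernel = "linear", true_g = amounts[keep], est_g = est[keep])
      }
    }
  }

  structure(list(
    n_events = length(dataset),
    recognition = recognition,
    fill_level = fill_level,
    volume = do.call(rbind, volume_rows),
    combination = do.call(rbind, combo_rows),
    predictions = do.call(rbind, pred_rows),
    unrecognized = unrecognized,
    protocol = cfg,
    seed = cfg$seed
  ), class = "drink_study")
}

#' @export
print.drink_study <- function(x, ...) {
  cat(sprintf("Fluid-intake assessment study: %d events, seed %d\n",
              x$n_events, x$seed))
  for (arm in names(x$recognition)) {
    r <- x$recognition[[arm]]
    cat(sprintf("  %s gesture accuracy: %.4f raw, %.4f postprocessed\n",
                arm, r$report_raw$accuracy, r$report_post$accuracy))
  }
  for (arm in names(x$fill_level)) {
    cat(sprintf("  %s fill level (linear SVR): ", arm))
    print(x$fill_level[[arm]]$linear)
  }
  inv <- x$volume[x$volume$category == "all" & x$volume$kernel == "linear" &
                    !x$volume$with_fill, ]
  for (i in seq_len(nrow(inv)))
    cat(sprintf("  %s volume %s: MAD %.2f g RMSE %.2f g\n",
                inv$arm[i], inv$scope[i], inv$mad[i], inv$rmse[i]))
  invisible(x)
}
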