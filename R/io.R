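# Plain-text session-bundle serialization: one CSV per sensor series
# (columns t, ax, ay, az, gx, gy, gz, label), one JSON metadata file per
# event, and one dataset-level manifest.  The format is versioned;
# readers reject unknown versions.

DATASET_FORMAT_VERSION <- "1"

series_to_df <- function(s) {
  data.frame(t = s$t,
             ax = s$acc[, 1], ay = s$acc[, 2], az = s$acc[, 3],
             gx = s$gyr[, 1], gy = s$gyr[, 2], gz = s$gyr[, 3],
             label = s$labels, stringsAsFactors = FALSE)
}

df_to_series <- function(df, placement, sample_rate_hz) {
  new_sensor_series(placement, df$t,
                    as.matrix(df[, c("ax", "ay", "az")]),
                    as.matrix(df[, c("gx", "gy", "gz")]),
                    df$label, sample_rate_hz)
}

#' Write a drinking dataset as a plain-text session bundle
#'
#' Each event becomes `<event_id>_wrist.csv`, `<event_id>_container.csv`
#' and `<event_id>_meta.json` (participant, fill level, sip size, true
#' amount, phase boundaries); `manifest.json` records the format version,
#' protocol and event list.  Output is deterministic: identical datasets
#' produce identical files.
#'
#' @param dataset A `drink_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- attr(dataset, "protocol")
  sm <- attr(dataset, "sip_model")
  for (ev in dataset) {
    base <- file.path(dir, ev$event_id)
    utils::write.csv(series_to_df(ev$wrist),
                     paste0(base, "_wrist.csv"), row.names = FALSE)
    utils::write.csv(series_to_df(ev$container),
                     paste0(base, "_container.csv"), row.names = FALSE)
    meta <- list(event_id = ev$event_id, participant = ev$participant,
                 fill_level_g = ev$fill_level_g, sip_size = ev$sip_size,
                 repetition = ev$repetition,
                 true_amount_g = ev$true_amount_g,
                 sample_rate_hz = ev$wrist$sample_rate_hz,
                 phases = ev$phases)
    jsonlite::write_json(meta, paste0(base, "_meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(format_version = DATASET_FORMAT_VERSION,
                   protocol = unclass(cfg),
                   sip_model = unclass(sm),
                   n_events = length(dataset),
                   event_ids = vapply(dataset, function(e) e$event_id,
                                      character(1)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session bundle written by [write_dataset()]
#'
#' @param dir Bundle directory containing `manifest.json`.
#' @return A `drink_dataset`.
#' @export
read_dataset <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path))
    stop(sprintf("no manifest.json under '%s'", dir), call. = FALSE)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  if (!identical(as.character(mf$format_version), DATASET_FORMAT_VERSION))
    stop(sprintf("unsupported dataset format version '%s'",
                 mf$format_version), call. = FALSE)
  events <- lapply(mf$event_ids, function(id) {
    base <- file.path(dir, id)
    meta <- jsonlite::read_json(paste0(base, "_meta.json"),
                                simplifyVector = TRUE)
    fs <- meta$sample_rate_hz
    wr <- utils::read.csv(paste0(base, "_wrist.csv"),
                          stringsAsFactors = FALSE)
    co <- utils::read.csv(paste0(base, "_container.csv"),
                          stringsAsFactors = FALSE)
    ev <- list(event_id = meta$event_id, participant = meta$participant,
               fill_level_g = meta$fill_level_g, sip_size = meta$sip_size,
               repetition = as.integer(meta$repetition),
               true_amount_g = meta$true_amount_g,
               wrist = df_to_series(wr, "wrist", fs),
               container = df_to_series(co, "container", fs),
               phases = as.data.frame(meta$phases))
    class(ev) <- "drink_event"
    ev
  })
  cfg <- mf$protocol
  cfg$n_participants <- as.integer(cfg$n_participants)
  cfg$repetitions <- as.integer(cfg$repetitions)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "drink_protocol"
  sm <- mf$sip_model
  sm$mean_g <- unlist(sm$mean_g)
  sm$sd_g <- unlist(sm$sd_g)
  class(sm) <- "sip_size_model"
  structure(events, class = "drink_dataset", protocol = cfg,
            sip_model = sm)
}

#' Write the tables of a finished study to disk
#'
#' Emits `summary.json` (headline metrics, seed, protocol),
#' `windows_<arm>.csv` (per-window true/raw/postprocessed labels),
#' `volume_metrics.csv`, `combination.csv` and `predictions.csv`
#' (per-event true vs estimated grams with model provenance).
#'
#' @param study A `drink_study` from [run_full_study()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (arm in names(study$recognition)) {
    utils::write.csv(study$recognition[[arm]]$windows,
                     file.path(dir, sprintf("windows_%s.csv", arm)),
                     row.names = FALSE)
  }
  utils::write.csv(study$volume, file.path(dir, "volume_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(study$combination, file.path(dir, "combination.csv"),
                   row.names = FALSE)
  utils::write.csv(study$predictions, file.path(dir, "predictions.csv"),
                   row.names = FALSE)
  summary <- list(
    seed = study$seed,
    n_events = study$n_events,
    protocol = unclass(study$protocol),
    unrecognized = as.list(study$unrecognized),
    recognition = lapply(study$recognition, function(r)
      list(accuracy_raw = r$report_raw$accuracy,
           accuracy_post = r$report_post$accuracy,
           f1_post = r$report_post$f1,
           window_samples = r$wcfg$window_samples,
           overlap_pct = r$wcfg$overlap_pct)),
    fill_level = lapply(study$fill_level, function(fl)
      list(linear = unclass(fl$linear)[c("mape", "mad", "rmse", "r2", "n")],
           gaussian = unclass(fl$gaussian)[c("mape", "mad", "rmse", "r2",
                                             "n")]))
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write a window-grid study as a heatmap-shaped CSV
#'
#' Rows are window sizes, columns overlap percentages, cells the
#' postprocessed (or raw) accuracy.
#'
#' @param grid_result Result of [run_window_grid()].
#' @param path Output CSV path.
#' @param postprocessed Use postprocessed accuracy (default) or raw.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid_result, path, postprocessed = TRUE) {
  g <- grid_result$grid
  val <- if (postprocessed) g$accuracy_post else g$accuracy
  wide <- stats::reshape(
    data.frame(window_samples = g$window_samples,
               overlap_pct = g$overlap_pct, accuracy = val),
    idvar = "window_samples", timevar = "overlap_pct",
    direction = "wide")
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}
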