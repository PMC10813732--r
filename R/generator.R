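# Synthetic dual-placement IMU drinking-session generator.
#
# Physical couplings built in (and relied on downstream):
#   * sip amount ~ truncated normal per sip-size category;
#   * sip duration grows monotonically with the drawn amount, with a
#     category-specific flow rate (larger sips are drawn faster) and a
#     per-participant speed factor;
#   * peak container tilt during the sip grows as the fill level drops
#     (an emptier cup must be tilted further to drink);
#   * the wrist channel equals the container motion plus a constant
#     per-participant orientation offset and 3x the container noise;
#   * the container is stationary (gravity-only accel, ~0 gyro) outside
#     the pre-sip..post-sip span.

# noise floors for the container sensor; wrist uses WRIST_NOISE_FACTOR x these
ACC_NOISE_SD_G <- 0.02
GYR_NOISE_SD_DPS <- 1.5
WRIST_NOISE_FACTOR <- 3

ACC_RANGE_G <- 16
GYR_RANGE_DPS <- 2000

smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

#' Draw sip amounts from a category's truncated normal
#'
#' Rejection sampling from `N(mean, sd)` truncated to
#' `[floor_g, cap_g]`.  Used by the generator; exported so the drawn
#' distribution can be checked against its configured moments.
#'
#' @param n Number of draws.
#' @param category Sip-size category name present in `model`.
#' @param model A [sip_size_model()].
#' @param cap_g Upper truncation bound in grams (the fill level).
#' @return Numeric vector of `n` amounts in grams.
#' @export
draw_sip_amount <- function(n, category, model, cap_g = Inf) {
  if (!category %in% names(model$mean_g))
    stop(sprintf("unknown sip-size category '%s'", category), call. = FALSE)
  if (cap_g <= model$floor_g)
    stop("cap_g must exceed the truncation floor", call. = FALSE)
  mu <- model$mean_g[[category]]
  sd <- model$sd_g[[category]]
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(n, mu, sd)
    out <- c(out, draw[draw >= model$floor_g & draw <= cap_g])
  }
  out[seq_len(n)]
}

# category-specific sip flow rate in g/s; increases with the category's
# mean amount so larger instructed sips are drawn proportionally faster
sip_flow_rate <- function(mean_g) 4 + 0.22 * mean_g

sip_duration_s <- function(amount_g, category, model, speed) {
  rate <- sip_flow_rate(model$mean_g[[category]])
  speed * (1 + amount_g / rate)
}

# per-participant latent traits; drawn once per dataset
participant_profiles <- function(n) {
  lapply(seq_len(n), function(p) {
    list(
      participant_id = sprintf("P%02d", p),
      roll_offset_deg = stats::runif(1, -15, 15),
      speed = stats::runif(1, 0.85, 1.15),
      reach_deg = stats::runif(1, 20, 35)
    )
  })
}

new_sensor_series <- function(placement, t, acc, gyr, labels, sample_rate_hz) {
  acc <- pmin(pmax(acc, -ACC_RANGE_G), ACC_RANGE_G)
  gyr <- pmin(pmax(gyr, -GYR_RANGE_DPS), GYR_RANGE_DPS)
  colnames(acc) <- c("x", "y", "z")
  colnames(gyr) <- c("x", "y", "z")
  structure(list(placement = placement, t = t, acc = acc, gyr = gyr,
                 labels = labels, sample_rate_hz = sample_rate_hz),
            class = "sensor_series")
}

#' Synthesize one labeled drinking event
#'
#' Builds the five-phase tilt/yaw trajectory for one drinking event and
#' renders it into the two sensor streams (wrist and container bottom),
#' sampled on a common clock.  Consumes the session RNG stream: callers
#' seed via `set.seed()` (as [generate_dataset()] does).
#'
#' @param profile Participant profile (internal list: id, roll offset,
#'   speed factor, reach angle).
#' @param fill_level_g Water mass in the cup before the sip (g).
#' @param sip_size Sip-size category name.
#' @param sip_model A [sip_size_model()].
#' @param cfg A [drink_protocol()].
#' @param repetition Repetition index (only recorded in the event id).
#' @return An object of class `drink_event`: metadata, `wrist` and
#'   `container` sensor series, and a `phases` data frame with 1-based
#'   sample `start`/`end` per phase.
#' @export
synthesize_event <- function(profile, fill_level_g, sip_size, sip_model,
                             cfg, repetition = 1L) {
  fs <- cfg$sample_rate_hz
  amount <- draw_sip_amount(1, sip_size, sip_model, cap_g = fill_level_g)

  dur <- c(
    grasp    = stats::runif(1, 0.5, 1.5),
    pre_sip  = stats::runif(1, 1, 2),
    sip      = sip_duration_s(amount, sip_size, sip_model, profile$speed),
    post_sip = stats::runif(1, 1, 2),
    release  = stats::runif(1, 0.5, 1.5)
  )
  n_k <- pmax(1L, as.integer(round(dur * fs)))
  n <- sum(n_k)
  ends <- cumsum(n_k)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  phases <- data.frame(phase = GESTURE_LEVELS, start = starts, end = ends,
                       stringsAsFactors = FALSE)
  labels <- rep(GESTURE_LEVELS, times = n_k)
  t <- (seq_len(n) - 1L) / fs

  # container tilt: emptier cup -> steeper peak tilt during the sip
  theta_peak <- 35 + 55 * (1 - fill_level_g / cfg$cup_capacity_g) +
    stats::rnorm(1, 0, 3)
  theta_peak <- min(max(theta_peak, 20), 100)
  ripple_phase <- stats::runif(1, 0, 2 * pi)

  seg_u <- function(k) {
    m <- n_k[[k]]
    if (m == 1L) return(0.5)
    (seq_len(m) - 1L) / (m - 1L)
  }
  theta <- c(
    rep(0, n_k[1]),
    theta_peak * smoothstep(seg_u(2)),
    theta_peak + 2 * sin(2 * pi * 1.2 * t[starts[3]:ends[3]] + ripple_phase),
    theta_peak * (1 - smoothstep(seg_u(4))),
    rep(0, n_k[5])
  )

  # wrist reach yaw: ramps up while grasping, back down on release
  psi <- c(
    profile$reach_deg * smoothstep(seg_u(1)),
    rep(profile$reach_deg, sum(n_k[2:4])),
    profile$reach_deg * (1 - smoothstep(seg_u(5)))
  )

  dtheta <- finite_diff(theta, fs)
  dpsi <- finite_diff(psi, fs)

  th_c <- theta * pi / 180
  acc_c <- cbind(0, sin(th_c), cos(th_c)) +
    matrix(stats::rnorm(3 * n, 0, ACC_NOISE_SD_G), n, 3)
  gyr_c <- cbind(dtheta, 0, 0) +
    matrix(stats::rnorm(3 * n, 0, GYR_NOISE_SD_DPS), n, 3)

  # wrist: container tilt + constant per-participant roll offset; a small
  # vertical linear-acceleration bump marks the lift and the put-down
  th_w <- (theta + profile$roll_offset_deg) * pi / 180
  lift <- numeric(n)
  lift[starts[2]:ends[2]] <- 0.06 * sin(pi * seg_u(2))
  lift[starts[4]:ends[4]] <- -0.06 * sin(pi * seg_u(4))
  acc_w <- cbind(0, sin(th_w), cos(th_w) + lift) +
    matrix(stats::rnorm(3 * n, 0, WRIST_NOISE_FACTOR * ACC_NOISE_SD_G), n, 3)
  gyr_w <- cbind(dtheta, 0, dpsi) +
    matrix(stats::rnorm(3 * n, 0, WRIST_NOISE_FACTOR * GYR_NOISE_SD_DPS), n, 3)

  event <- list(
    event_id = sprintf("%s_F%03d_%s_R%d", profile$participant_id,
                       as.integer(fill_level_g), sip_size,
                       as.integer(repetition)),
    participant = profile$participant_id,
    fill_level_g = fill_level_g,
    sip_size = sip_size,
    repetition = as.integer(repetition),
    true_amount_g = amount,
    wrist = new_sensor_series("wrist", t, acc_w, gyr_w, labels, fs),
    container = new_sensor_series("container", t, acc_c, gyr_c, labels, fs),
    phases = phases
  )
  class(event) <- "drink_event"
  event
}

#' Generate a full synthetic drinking-session dataset
#'
#' Runs the complete protocol grid: every participant performs every
#' (fill level, sip size) cell `repetitions` times, yielding
#' `n_participants * fills * sizes * repetitions` labeled events (1008
#' under the default 12 x 7 x 3 x 4 protocol; 84 per participant).
#' Identical `cfg$seed` yields identical output.
#'
#' @param cfg A [drink_protocol()].
#' @param sip_model A [sip_size_model()].
#' @return An object of class `drink_dataset`: a list of `drink_event`s
#'   with the generating `cfg` and `sip_model` attached as attributes.
#' @export
#' @examples
#' ds <- generate_dataset(drink_protocol(n_participants = 1, repetitions = 1,
#'                                       fill_levels_g = c(100, 400),
#'                                       seed = 7))
#' length(ds)  # 2 fills x 3 sizes
generate_dataset <- function(cfg = drink_protocol(),
                             sip_model = sip_size_model()) {
  validate_protocol(cfg)
  if (min(cfg$fill_levels_g) <= sip_model$floor_g)
    stop("invalid protocol config: field 'fill_levels_g' must exceed the sip",
         " amount floor", call. = FALSE)
  set.seed(cfg$seed)
  profiles <- participant_profiles(cfg$n_participants)
  events <- vector("list",
                   cfg$n_participants * length(cfg$fill_levels_g) *
                     length(cfg$sip_sizes) * cfg$repetitions)
  i <- 0L
  for (p in seq_len(cfg$n_participants)) {
    for (fill in cfg$fill_levels_g) {
      for (size in cfg$sip_sizes) {
        for (rep_i in seq_len(cfg$repetitions)) {
          i <- i + 1L
          events[[i]] <- synthesize_event(profiles[[p]], fill, size,
                                          sip_model, cfg, rep_i)
        }
      }
    }
  }
  structure(events, class = "drink_dataset", protocol = cfg,
            sip_model = sip_model)
}

#' @export
print.drink_dataset <- function(x, ...) {
  cfg <- attr(x, "protocol")
  cat(sprintf("Synthetic drinking dataset: %d events, %d participants, seed %d\n",
              length(x), cfg$n_participants, cfg$seed))
  invisible(x)
}

#' @export
print.drink_event <- function(x, ...) {
  cat(sprintf("Drinking event %s: fill %g g, %s sip, %.2f g taken, %d samples\n",
              x$event_id, x$fill_level_g, x$sip_size, x$true_amount_g,
              length(x$wrist$t)))
  invisible(x)
}

# sip interval from the ground-truth phase table, 1-based inclusive
true_sip_interval <- function(event) {
  row <- event$phases[event$phases$phase == "sip", ]
  c(start = row$start, end = row$end)
}

true_motion_interval <- function(event) {
  c(start = event$phases$start[event$phases$phase == "pre_sip"],
    end = event$phases$end[event$phases$phase == "post_sip"])
}
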