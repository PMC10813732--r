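#' Gesture labels used throughout the pipeline
#'
#' The five phases of one drinking event, in temporal order: the hand takes
#' the container (`grasp`), lifts it to the mouth (`pre_sip`), water is taken
#' in (`sip`), the container is put back down (`post_sip`) and let go
#' (`release`).  The wrist-worn arm sees all five; the container-mounted arm
#' only moves during `pre_sip`..`post_sip` and is classified over those three.
#'
#' @format Character vectors of phase names.
#' @export
GESTURE_LEVELS <- c("grasp", "pre_sip", "sip", "post_sip", "release")

#' @rdname GESTURE_LEVELS
#' @export
CONTAINER_LEVELS <- c("pre_sip", "sip", "post_sip")

#' Experimental protocol configuration
#'
#' Describes the drinking-session grid that the synthetic generator emulates:
#' every participant performs every (fill level, sip size) cell a fixed number
#' of times, so the dataset factorizes exactly as
#' `n_participants * length(fill_levels_g) * length(sip_sizes) * repetitions`
#' events.
#'
#' @param n_participants Number of participants (default 12).
#' @param fill_levels_g Water masses in the cup before the sip, in grams
#'   (default 100, 150, ..., 400 g).
#' @param sip_sizes Instructed sip-size categories (default
#'   `c("small", "medium", "large")`).
#' @param repetitions Repetitions per (fill level, sip size) cell (default 4).
#' @param sample_rate_hz IMU sampling rate in Hz (default 128).
#' @param cup_capacity_g Full capacity of the cup in grams (default 500).
#' @param seed Integer seed controlling all randomness of generation.
#' @return An object of class `drink_protocol`.
#' @export
#' @examples
#' cfg <- drink_protocol(n_participants = 2, repetitions = 1)
#' cfg$n_participants
drink_protocol <- function(n_participants = 12,
                           fill_levels_g = seq(100, 400, by = 50),
                           sip_sizes = c("small", "medium", "large"),
                           repetitions = 4,
                           sample_rate_hz = 128,
                           cup_capacity_g = 500,
                           seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    fill_levels_g = as.numeric(fill_levels_g),
    sip_sizes = as.character(sip_sizes),
    repetitions = as.integer(repetitions),
    sample_rate_hz = as.numeric(sample_rate_hz),
    cup_capacity_g = as.numeric(cup_capacity_g),
    seed = as.integer(seed)
  )
  class(cfg) <- "drink_protocol"
  validate_protocol(cfg)
  cfg
}

validate_protocol <- function(cfg) {
  stop_field <- function(field, msg) {
    stop(sprintf("invalid protocol config: field '%s' %s", field, msg),
         call. = FALSE)
  }
  if (is.na(cfg$n_participants) || cfg$n_participants < 1L)
    stop_field("n_participants", "must be a positive integer")
  if (length(cfg$fill_levels_g) == 0 || anyNA(cfg$fill_levels_g))
    stop_field("fill_levels_g", "must be non-empty and free of NA")
  if (is.na(cfg$cup_capacity_g) || cfg$cup_capacity_g <= 0)
    stop_field("cup_capacity_g", "must be > 0")
  if (any(cfg$fill_levels_g <= 0 | cfg$fill_levels_g > cfg$cup_capacity_g))
    stop_field("fill_levels_g", "must lie in (0, cup_capacity_g]")
  if (length(cfg$sip_sizes) == 0 || anyDuplicated(cfg$sip_sizes))
    stop_field("sip_sizes", "must be non-empty and unique")
  if (is.na(cfg$repetitions) || cfg$repetitions < 1L)
    stop_field("repetitions", "must be >= 1")
  if (is.na(cfg$sample_rate_hz) || cfg$sample_rate_hz <= 0)
    stop_field("sample_rate_hz", "must be > 0")
  if (is.na(cfg$seed))
    stop_field("seed", "must be an integer")
  invisible(cfg)
}

#' Sip-size amount model
#'
#' Per-category truncated-normal model for the mass of water taken in one
#' sip.  Defaults are the per-category means and standard deviations of the
#' actual sip amounts observed in the drinking protocol: large 53.82 +/- 8.58
#' g, medium 27.23 +/- 6.20 g, small 10.71 +/- 5.56 g.  Draws below
#' `floor_g` (or above the current fill level) are rejected and redrawn.
#'
#' @param mean_g Named numeric vector of per-category mean sip amounts (g).
#' @param sd_g Named numeric vector of per-category standard deviations (g).
#' @param floor_g Truncation floor in grams (default 1 g, must be > 0).
#' @return An object of class `sip_size_model`.
#' @export
sip_size_model <- function(mean_g = c(small = 10.71, medium = 27.23,
                                      large = 53.82),
                           sd_g = c(small = 5.56, medium = 6.20,
                                    large = 8.58),
                           floor_g = 1) {
  if (!identical(sort(names(mean_g)), sort(names(sd_g))))
    stop("sip_size_model: mean_g and sd_g must share category names",
         call. = FALSE)
  ord <- names(mean_g)[order(mean_g)]
  if (is.unsorted(mean_g[ord], strictly = TRUE))
    stop("sip_size_model: category means must be strictly ordered",
         call. = FALSE)
  if (any(sd_g <= 0)) stop("sip_size_model: sd_g must be > 0", call. = FALSE)
  if (floor_g <= 0) stop("sip_size_model: floor_g must be > 0", call. = FALSE)
  structure(list(mean_g = mean_g, sd_g = sd_g[names(mean_g)],
                 floor_g = floor_g),
            class = "sip_size_model")
}

#' @export
print.drink_protocol <- function(x, ...) {
  cat("Drinking-session protocol\n")
  cat(sprintf("  participants : %d\n", x$n_participants))
  cat(sprintf("  fill levels  : %s g\n",
              paste(x$fill_levels_g, collapse = ", ")))
  cat(sprintf("  sip sizes    : %s\n", paste(x$sip_sizes, collapse = ", ")))
  cat(sprintf("  repetitions  : %d\n", x$repetitions))
  cat(sprintf("  sample rate  : %g Hz, cup capacity %g g, seed %d\n",
              x$sample_rate_hz, x$cup_capacity_g, x$seed))
  n <- x$n_participants * length(x$fill_levels_g) * length(x$sip_sizes) *
    x$repetitions
  cat(sprintf("  events       : %d\n", n))
  invisible(x)
}
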