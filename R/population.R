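#' Draw a synthetic spore population with ground truth
#'
#' Samples per-spore ground truth from the distributions in the configuration:
#' position, initial radius, germination flag (Bernoulli, optionally modulated
#' by a monotone-decreasing load coupling), germination lag, fungal area
#' doubling time, and initial intracellular bacterial load. Rendering
#' randomness (per-frame area jitter, germ-tube direction) is pre-drawn here so
#' that all downstream rendering is a deterministic function of the returned
#' population.
#'
#' Uses the current RNG stream; call `set.seed()` (or [run_pipeline()], which
#' seeds from the config) for reproducibility.
#'
#' @param config a [simulation_config()].
#' @return a `data.frame` of class `spore_population` with one row per spore:
#'   `spore_id`, `center_y`, `center_x`, `radius_px`, `germinating`, `lag_min`,
#'   `doubling_time_min`, `load0_au`, `germ_prob`, `tube_dir`; the config and
#'   the pre-drawn jitter matrix are attached as attributes.
#' @examples
#' set.seed(1)
#' pop <- generate_population(simulation_config(n_spores = 5))
#' pop$germinating
#' @export
generate_population <- function(config) {
  validate_simulation_config(config)
  n <- config$n_spores
  if (n == 0L) {
    pop <- data.frame(spore_id = integer(0), center_y = numeric(0),
                      center_x = numeric(0), radius_px = numeric(0),
                      germinating = logical(0), lag_min = numeric(0),
                      doubling_time_min = numeric(0), load0_au = numeric(0),
                      germ_prob = numeric(0), tube_dir = integer(0))
    attr(pop, "config") <- config
    attr(pop, "area_jitter") <- matrix(numeric(0), 0, config$n_frames)
    class(pop) <- c("spore_population", "data.frame")
    return(pop)
  }

  centers <- place_spores(n, config)
  radius <- pmax(2, stats::rnorm(n, config$spore_radius_mean, config$spore_radius_sd))
  load0 <- stats::rlnorm(n, config$initial_load_distribution$meanlog,
                         config$initial_load_distribution$sdlog)
  p <- rep(config$germination_probability, n)
  cpl <- config$load_germination_coupling
  if (cpl$type == "logistic") {
    # monotone-decreasing modulation with log-load, 2/(1+exp(.)) so a spore at
    # the midpoint keeps the baseline probability
    p <- pmin(1, p * 2 / (1 + exp(cpl$slope * (log(load0) - cpl$midpoint))))
  }
  germinating <- stats::runif(n) < p
  lag <- pmax(0, stats::rnorm(n, config$lag_mean, config$lag_sd))
  td <- pmax(10, stats::rnorm(n, config$fungal_doubling_time_mean,
                              config$fungal_doubling_time_sd))
  tube_dir <- sample.int(4L, n, replace = TRUE)  # cardinal directions
  jitter <- matrix(stats::rnorm(n * config$n_frames, 0, config$area_jitter_sd),
                   nrow = n)

  pop <- data.frame(spore_id = seq_len(n),
                    center_y = centers[, 1], center_x = centers[, 2],
                    radius_px = radius, germinating = germinating,
                    lag_min = lag, doubling_time_min = td,
                    load0_au = load0, germ_prob = p, tube_dir = tube_dir)
  attr(pop, "config") <- config
  attr(pop, "area_jitter") <- jitter
  class(pop) <- c("spore_population", "data.frame")
  pop
}

place_spores <- function(n, config) {
  ny <- config$image_shape[1]; nx <- config$image_shape[2]
  if (config$placement == "random") {
    margin <- 3 * config$spore_radius_mean
    return(cbind(stats::runif(n, margin, ny - margin),
                 stats::runif(n, margin, nx - margin)))
  }
  cols <- ceiling(sqrt(n))
  rows <- ceiling(n / cols)
  ch <- ny / rows; cw <- nx / cols
  idx <- seq_len(n) - 1L
  cy <- (idx %/% cols + 0.5) * ch + stats::runif(n, -0.1 * ch, 0.1 * ch)
  cx <- (idx %% cols + 0.5) * cw + stats::runif(n, -0.1 * cw, 0.1 * cw)
  cbind(cy, cx)
}

frame_times <- function(config, frames = seq_len(config$n_frames) - 1L) {
  frames * config$frame_interval
}

#' True per-frame area and load series of a population
#'
#' The true projected area of a germinating spore is constant at
#' `A0 = pi * r^2` until its lag, then grows exponentially with the spore's
#' doubling time: `A(t) = A0 * 2^((t - lag) / T_D)`. Non-germinating spores
#' stay constant. The true bacterial load grows exponentially with the
#' bacterial doubling time after the bacterial lag.
#'
#' @param pop a [generate_population()] result.
#' @param frames 0-based frame indices (default: all frames in the config).
#' @return a numeric matrix, spores x frames (pixels^2 for area, arbitrary
#'   fluorescence units for load).
#' @export
truth_area_series <- function(pop, frames = NULL) {
  config <- attr(pop, "config")
  if (is.null(frames)) frames <- seq_len(config$n_frames) - 1L
  t_min <- frame_times(config, frames)
  a0 <- pi * pop$radius_px^2
  out <- matrix(a0, nrow = nrow(pop), ncol = length(t_min))
  if (nrow(pop) == 0L) return(out)
  for (j in seq_along(t_min)) {
    grow <- pop$germinating & t_min[j] > pop$lag_min
    out[grow, j] <- a0[grow] *
      2^((t_min[j] - pop$lag_min[grow]) / pop$doubling_time_min[grow])
  }
  dimnames(out) <- list(pop$spore_id, frames)
  out
}

#' @rdname truth_area_series
#' @export
truth_load_series <- function(pop, frames = NULL) {
  config <- attr(pop, "config")
  if (is.null(frames)) frames <- seq_len(config$n_frames) - 1L
  t_min <- frame_times(config, frames)
  if (nrow(pop) == 0L)
    return(matrix(numeric(0), 0L, length(t_min)))
  dt <- outer(rep(1, nrow(pop)), t_min) - config$bacterial_lag
  dt[dt < 0] <- 0
  out <- pop$load0_au * 2^(dt / config$bacterial_doubling_time)
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(pop))
  dimnames(out) <- list(pop$spore_id, frames)
  out
}

#' Simulate a single-cell bacterial volume (voxel-count) series
#'
#' Emulates a followed single injected bacterium: a lag phase at the initial
#' volume followed by exponential growth, with multiplicative log-normal
#' measurement noise. Used to exercise the maximum-growth-window doubling-time
#' estimator.
#'
#' @param duration_min total duration (default 900 = 15 h).
#' @param interval_min sampling interval (default 60 min, chosen so that the
#'   default 5-point maximum-growth window spans a substantial fraction of the
#'   post-lag growth phase; see the methods vignette).
#' @param lag_min lag before growth resumes (default 360 = 6 h).
#' @param doubling_time_min exponential doubling time (default 102 min ~ 1.7 h).
#' @param initial initial voxel count (arbitrary units).
#' @param noise_sd sd of the multiplicative log-normal noise (0.05 = 5%).
#' @return data.frame with `time_min` and `voxels`.
#' @export
simulate_voxel_series <- function(duration_min = 900, interval_min = 60,
                                  lag_min = 360, doubling_time_min = 102,
                                  initial = 100, noise_sd = 0.05) {
  stopifnot(duration_min > 0, interval_min > 0, doubling_time_min > 0,
            lag_min >= 0, initial > 0, noise_sd >= 0)
  t <- seq(0, duration_min, by = interval_min)
  v <- initial * 2^(pmax(0, t - lag_min) / doubling_time_min)
  v <- v * exp(stats::rnorm(length(v), 0, noise_sd))
  data.frame(time_min = t, voxels = v)
}
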