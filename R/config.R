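#' Simulation configuration for the synthetic time-lapse generator
#'
#' Bundles every parameter of the synthetic spore cohort: imaging geometry,
#' acquisition cadence, spore geometry, germination/lag/growth distributions,
#' intracellular bacterial load dynamics, the load-germination coupling, and
#' the imaging noise model. Defaults reproduce the acquisition used throughout
#' the package: 15-min frames over a 16-h course, spores that lag for a few
#' hours and then grow exponentially (non-host-strain doubling time
#' 98 +/- 13.5 min) while extending a germ tube, and bacteria that resume
#' growth after a ~6-h lag with a doubling time of ~1.7 h.
#'
#' @param image_shape integer(2), image size in pixels (y, x), or `NULL` to
#'   auto-size a jittered grid large enough that spore footprints (at the
#'   rendering cap, including the germ tube) can never touch or leave the
#'   frame.
#' @param n_frames number of frames; frame f is acquired at `f * frame_interval`
#'   minutes, `f = 0 .. n_frames - 1`.
#' @param frame_interval minutes between frames.
#' @param n_spores number of spores; 0 gives an empty population.
#' @param spore_radius_mean,spore_radius_sd initial spore radius (pixels),
#'   normal, truncated at 2 px.
#' @param germination_probability baseline probability that a spore germinates.
#' @param lag_mean,lag_sd germination lag (minutes), normal, truncated at 0.
#' @param fungal_doubling_time_mean,fungal_doubling_time_sd per-spore area
#'   doubling time (minutes), normal, truncated at 10 min.
#' @param germ_tube_rate germ-tube elongation (pixels per frame) after lag.
#' @param germ_tube_width germ-tube width in pixels.
#' @param germ_tube_max_len rendered germ-tube length cap in pixels; growth
#'   beyond the cap is absorbed by the spore body.
#' @param bacterial_doubling_time intracellular bacterial doubling time
#'   (minutes).
#' @param bacterial_lag minutes before intracellular bacteria resume growth.
#' @param initial_load_distribution list(meanlog, sdlog): log-normal initial
#'   bacterial load per spore (arbitrary fluorescence units).
#' @param load_germination_coupling list with `type = "none"` or
#'   `type = "logistic"` plus `midpoint` (log a.u.) and `slope`; the logistic
#'   form multiplies `germination_probability` by
#'   `2 / (1 + exp(slope * (log(load) - midpoint)))` clipped to \[0, 1\], a
#'   monotone decrease of germination probability with log-load.
#' @param noise_model list(gaussian_sd, poisson): additive Gaussian sd on
#'   rendered intensities (on the 0-1 widefield scale) and an optional Poisson
#'   resampling of fluorescence counts.
#' @param area_jitter_sd multiplicative log-normal jitter applied to the
#'   rendered (not the true) per-frame area, emulating focus/segmentation
#'   variability of the measured series.
#' @param max_render_fold rendered morphology saturates at this fold of the
#'   initial area; the true area series keeps growing. The analysis only uses
#'   the early germination phase (the roundness filter removes older
#'   germlings), and the cap keeps rendered footprints bounded.
#' @param n_z number of z-slices written per channel; fluorescence is placed in
#'   the middle slice so the z sum-projection equals the true load.
#' @param placement `"grid"` (jittered grid, default) or `"random"`.
#' @param seed integer seed recorded in the config and used by
#'   [run_pipeline()].
#'
#' @return an object of class `simulation_config` (a validated list).
#' @seealso [generate_population()], [render_timelapse()]
#' @export
simulation_config <- function(image_shape = c(512L, 512L),
                              n_frames = 64L,
                              frame_interval = 15,
                              n_spores = 20L,
                              spore_radius_mean = 6,
                              spore_radius_sd = 0.75,
                              germination_probability = 0.52,
                              lag_mean = 240,
                              lag_sd = 60,
                              fungal_doubling_time_mean = 98,
                              fungal_doubling_time_sd = 13.5,
                              germ_tube_rate = 2,
                              germ_tube_width = 4,
                              germ_tube_max_len = 40,
                              bacterial_doubling_time = 102,
                              bacterial_lag = 360,
                              initial_load_distribution = list(meanlog = log(1000), sdlog = 0.4),
                              load_germination_coupling = list(type = "none"),
                              noise_model = list(gaussian_sd = 0.02, poisson = FALSE),
                              area_jitter_sd = 0.05,
                              max_render_fold = 12,
                              n_z = 3L,
                              placement = c("grid", "random"),
                              seed = 1L) {
  placement <- match.arg(placement)
  if (is.null(image_shape)) {
    # worst-case footprint: capped body radius (with jitter headroom) + tube
    r_max <- spore_radius_mean + 3 * spore_radius_sd
    fp <- ceiling(1.2 * r_max * sqrt(max_render_fold) + germ_tube_max_len)
    spacing <- 2L * fp + 6L
    cols <- ceiling(sqrt(max(1L, n_spores)))
    rows <- ceiling(max(1L, n_spores) / cols)
    image_shape <- c(rows * spacing, cols * spacing)
  }
  cfg <- list(
    image_shape = as.integer(image_shape),
    n_frames = as.integer(n_frames),
    frame_interval = frame_interval,
    n_spores = as.integer(n_spores),
    spore_radius_mean = spore_radius_mean,
    spore_radius_sd = spore_radius_sd,
    germination_probability = germination_probability,
    lag_mean = lag_mean, lag_sd = lag_sd,
    fungal_doubling_time_mean = fungal_doubling_time_mean,
    fungal_doubling_time_sd = fungal_doubling_time_sd,
    germ_tube_rate = germ_tube_rate,
    germ_tube_width = germ_tube_width,
    germ_tube_max_len = germ_tube_max_len,
    bacterial_doubling_time = bacterial_doubling_time,
    bacterial_lag = bacterial_lag,
    initial_load_distribution = initial_load_distribution,
    load_germination_coupling = load_germination_coupling,
    noise_model = noise_model,
    area_jitter_sd = area_jitter_sd,
    max_render_fold = max_render_fold,
    n_z = as.integer(n_z),
    placement = placement,
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (length(cfg$image_shape) != 2L || any(cfg$image_shape < 16L))
    stop("image_shape must be two integers >= 16", call. = FALSE)
  if (cfg$n_frames < 1L) stop("n_frames must be >= 1", call. = FALSE)
  durs <- c(frame_interval = cfg$frame_interval,
            fungal_doubling_time_mean = cfg$fungal_doubling_time_mean,
            bacterial_doubling_time = cfg$bacterial_doubling_time)
  if (any(durs <= 0)) stop("all durations must be > 0", call. = FALSE)
  if (cfg$lag_mean < 0 || cfg$lag_sd < 0)
    stop("lag parameters must be non-negative", call. = FALSE)
  if (cfg$germination_probability < 0 || cfg$germination_probability > 1)
    stop("germination_probability must be in [0, 1]", call. = FALSE)
  if (cfg$n_spores < 0L) stop("n_spores must be >= 0", call. = FALSE)
  if (cfg$spore_radius_mean <= 0 || cfg$spore_radius_sd < 0)
    stop("invalid spore radius distribution", call. = FALSE)
  ild <- cfg$initial_load_distribution
  if (!is.list(ild) || is.null(ild$meanlog) || is.null(ild$sdlog) || ild$sdlog < 0)
    stop("initial_load_distribution needs meanlog and sdlog >= 0", call. = FALSE)
  cpl <- cfg$load_germination_coupling
  if (!is.list(cpl) || is.null(cpl$type) || !cpl$type %in% c("none", "logistic"))
    stop("load_germination_coupling$type must be 'none' or 'logistic'", call. = FALSE)
  if (cpl$type == "logistic" && (is.null(cpl$midpoint) || is.null(cpl$slope) || cpl$slope < 0))
    stop("logistic coupling needs midpoint and slope >= 0", call. = FALSE)
  nm <- cfg$noise_model
  if (!is.list(nm) || is.null(nm$gaussian_sd) || nm$gaussian_sd < 0)
    stop("noise_model needs gaussian_sd >= 0", call. = FALSE)
  if (cfg$area_jitter_sd < 0) stop("area_jitter_sd must be >= 0", call. = FALSE)
  if (cfg$max_render_fold < 1) stop("max_render_fold must be >= 1", call. = FALSE)
  if (cfg$n_z < 1L) stop("n_z must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config:",
      sprintf("%dx%d px, %d frames @ %g min, %d spores",
              x$image_shape[1], x$image_shape[2], x$n_frames,
              x$frame_interval, x$n_spores), "\n")
  cat(sprintf("  germination p=%.3g, lag %g+/-%g min, fungal T_D %g+/-%g min\n",
              x$germination_probability, x$lag_mean, x$lag_sd,
              x$fungal_doubling_time_mean, x$fungal_doubling_time_sd))
  cat(sprintf("  bacterial T_D %g min after %g min lag; coupling: %s; seed %d\n",
              x$bacterial_doubling_time, x$bacterial_lag,
              x$load_germination_coupling$type, x$seed))
  invisible(x)
}

#' Segmentation parameters
#'
#' Thresholds and filters applied when integrating the three probability maps
#' (whole cell, contour, spore body) into labeled spore objects.
#'
#' @param cell_threshold,contour_threshold,body_threshold map binarization
#'   thresholds in \[0, 1\]. Cell and body maps binarize at `>= threshold`;
#'   contour pixels are those strictly above `contour_threshold`, so a
#'   threshold of 1 disables contour splitting altogether.
#' @param min_roundness objects with roundness (4*pi*area/perimeter^2) below
#'   this are discarded; the default 0.6 removes elongated germlings so that
#'   only early germinating spores are retained.
#' @param min_area minimum object area in pixels^2.
#' @param connectivity 4 or 8, pixel connectivity used for labeling.
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(cell_threshold = 0.5,
                                contour_threshold = 0.5,
                                body_threshold = 0.5,
                                min_roundness = 0.6,
                                min_area = 30,
                                connectivity = 8L) {
  thr <- c(cell_threshold, contour_threshold, body_threshold)
  if (any(thr < 0 | thr > 1)) stop("thresholds must be in [0, 1]", call. = FALSE)
  if (min_roundness < 0 || min_roundness > 1)
    stop("min_roundness must be in [0, 1]", call. = FALSE)
  if (min_area < 0) stop("min_area must be >= 0", call. = FALSE)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8", call. = FALSE)
  structure(list(cell_threshold = cell_threshold,
                 contour_threshold = contour_threshold,
                 body_threshold = body_threshold,
                 min_roundness = min_roundness,
                 min_area = min_area,
                 connectivity = as.integer(connectivity)),
            class = "segmentation_params")
}

#' Germination-call parameters
#'
#' A tracked spore is called germinating when its projected area reaches
#' `fold_threshold` times its initial area within the first `window` minutes
#' (default: 1.5-fold within 10 h). Projected area serves as the volume proxy.
#'
#' @param fold_threshold fold-change threshold (> 1).
#' @param window evaluation window in minutes from the start of the track.
#' @return an object of class `germination_params`.
#' @export
germination_params <- function(fold_threshold = 1.5, window = 600) {
  if (fold_threshold <= 1) stop("fold_threshold must be > 1", call. = FALSE)
  if (window <= 0) stop("window must be > 0", call. = FALSE)
  structure(list(fold_threshold = fold_threshold, window = window),
            class = "germination_params")
}

#' Probability-map corruption parameters
#'
#' Controls how far the simulated probability maps depart from the ground
#' truth: a Gaussian blur (as produced by a soft segmentation backend),
#' additive Gaussian pixel noise, and an optional extra dilation of the
#' contour ridge. All zero reproduces the truth masks exactly.
#'
#' @param blur_sigma Gaussian blur sigma (pixels) for cell and body maps.
#' @param contour_blur_sigma blur sigma for the contour map.
#' @param noise_sd additive Gaussian noise sd on all three maps.
#' @param contour_dilation extra dilation (pixels) of the contour ridge.
#' @return an object of class `map_corruption`.
#' @export
map_corruption <- function(blur_sigma = 1, contour_blur_sigma = 0.5,
                           noise_sd = 0.05, contour_dilation = 0L) {
  if (any(c(blur_sigma, contour_blur_sigma, noise_sd, contour_dilation) < 0))
    stop("corruption parameters must be >= 0", call. = FALSE)
  structure(list(blur_sigma = blur_sigma,
                 contour_blur_sigma = contour_blur_sigma,
                 noise_sd = noise_sd,
                 contour_dilation = as.integer(contour_dilation)),
            class = "map_corruption")
}

#' Read or write a simulation configuration as a flat YAML file
#'
#' @param path file path.
#' @param config a [simulation_config()] object (for writing).
#' @return `read_simulation_config()` returns a `simulation_config`;
#'   `write_simulation_config()` returns `path` invisibly.
#' @export
read_simulation_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(simulation_config, raw)
}

#' @rdname read_simulation_config
#' @export
write_simulation_config <- function(config, path) {
  validate_simulation_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
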