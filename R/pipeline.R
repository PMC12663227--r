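#' Segment a sequence of probability maps into filtered label images
#'
#' Applies [integrate_maps()] and [filter_objects()] to each frame.
#'
#' @param maps_list list of `probability_maps`, one per frame.
#' @param params a [segmentation_params()].
#' @return list of integer label matrices.
#' @export
segment_stack <- function(maps_list, params = segmentation_params()) {
  lapply(maps_list, function(m) filter_objects(integrate_maps(m, params), params))
}

#' Run the full synthetic pipeline: simulate, segment, track, quantify
#'
#' Generates a synthetic spore population from `config`, simulates backend
#' probability maps from the rendered truth masks, integrates and filters
#' them, tracks the objects, measures the per-track parameters, and
#' summarizes germination and growth. All randomness derives from
#' `config$seed` (one global RNG stream), so a rerun with the same
#' configuration is bit-identical. When `out_dir` is given, the track
#' assignments, per-frame metrics, per-spore summary and a run manifest are
#' written there as CSV/JSON with provenance headers.
#'
#' @param config a [simulation_config()].
#' @param seg a [segmentation_params()].
#' @param germ a [germination_params()].
#' @param corruption a [map_corruption()].
#' @param out_dir optional output directory (created if missing).
#' @param measure_fluor set `FALSE` to skip fluorescence rendering and load
#'   measurement (faster; `load_au` becomes `NA`).
#' @param compute_length set `FALSE` to skip skeletonization.
#' @return list of class `pipeline_result`: `population`, `tracks`,
#'   `metrics`, `summary`, `config`, plus the parameter objects.
#' @export
run_pipeline <- function(config = simulation_config(),
                         seg = segmentation_params(),
                         germ = germination_params(),
                         corruption = map_corruption(),
                         out_dir = NULL,
                         measure_fluor = TRUE,
                         compute_length = TRUE) {
  validate_simulation_config(config)
  set.seed(config$seed)
  pop <- generate_population(config)
  frames <- seq_len(config$n_frames) - 1L

  labels <- vector("list", length(frames))
  fluor <- if (measure_fluor) vector("list", length(frames)) else NULL
  loads <- if (measure_fluor) truth_load_series(pop) else NULL
  for (k in seq_along(frames)) {
    mk <- render_frame_masks(pop, config, frames[k])
    if (measure_fluor) {
      fluor[[k]] <- fluor_frame(mk$labels, loads[, k],
                                config$noise_model$gaussian_sd)
    }
    maps <- simulate_probability_maps(mk, corruption)
    labels[[k]] <- filter_objects(integrate_maps(maps, seg), seg)
  }

  tracks <- build_tracks(labels, frames)
  metrics <- measure_tracks(tracks, labels, fluor,
                            frame_interval = config$frame_interval,
                            compute_length = compute_length)
  summ <- if (nrow(metrics) > 0L) summarize_tracks(metrics, germ) else
    data.frame(track_id = integer(0))

  res <- structure(list(population = pop, tracks = tracks, metrics = metrics,
                        summary = summ, config = config, seg = seg,
                        germ = germ, corruption = corruption),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

# per-frame fluorescence z sum-projection: the spore's true load spread
# uniformly over its mask, plus Gaussian noise on the frame's intensity scale
fluor_frame <- function(lab, load_vec, gaussian_sd) {
  fl <- matrix(0, nrow(lab), ncol(lab))
  if (length(load_vec) > 0L && max(lab) > 0L) {
    npix <- tabulate(lab[lab > 0L], nbins = length(load_vec))
    for (i in which(npix > 0L)) fl[lab == i] <- load_vec[i] / npix[i]
  }
  if (gaussian_sd > 0 && max(fl) > 0) {
    noisy <- fl + stats::rnorm(length(fl), 0, gaussian_sd * max(fl))
    noisy[noisy < 0] <- 0
    fl[] <- noisy
  }
  fl
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- res$config$seed
  write_result_csv(res$tracks, file.path(out_dir, "track_assignments.csv"),
                   seed, res$config)
  write_result_csv(res$metrics, file.path(out_dir, "track_metrics.csv"),
                   seed, res$config)
  write_result_csv(res$summary, file.path(out_dir, "spore_summary.csv"),
                   seed, res$config)
  manifest <- list(sporetrack_version =
                     as.character(utils::packageVersion("sporetrack")),
                   seed = seed, config = unclass(res$config),
                   config_hash = config_hash(res$config),
                   segmentation = unclass(res$seg),
                   germination = unclass(res$germ),
                   corruption = unclass(res$corruption),
                   n_tracks = length(unique(res$tracks$track_id)))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d spores simulated, %d tracks, %d track-frames\n",
              nrow(x$population), length(unique(x$tracks$track_id)),
              nrow(x$metrics)))
  if (nrow(x$summary) > 0L && "germinating" %in% names(x$summary)) {
    cat(sprintf("  germinating calls: %d TRUE / %d FALSE / %d NA\n",
                sum(x$summary$germinating %in% TRUE),
                sum(x$summary$germinating %in% FALSE),
                sum(is.na(x$summary$germinating))))
  }
  invisible(x)
}
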