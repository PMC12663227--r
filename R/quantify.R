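#' Per-track time series of the four spore parameters
#'
#' For every (track, frame) assignment, measures the four per-spore
#' parameters: (1) projected area in pixels^2 (the volume proxy), (2) skeleton
#' length in pixels (cumulative length of the medial-axis skeleton),
#' (3) roundness, and (4) bacterial load in arbitrary units (summed
#' fluorescence of the z sum-projection within the object mask). Frames where
#' a track has no assignment are absent, never interpolated.
#'
#' @param tracks a [build_tracks()] result.
#' @param labels list of label matrices the tracks were built from.
#' @param fluor optional list of fluorescence z sum-projection matrices (one
#'   per frame, see [fluor_projection()]); if missing, load is `NA`.
#' @param frame_interval minutes between frames.
#' @param compute_length set `FALSE` to skip the (relatively expensive)
#'   skeletonization.
#' @return data.frame of class `track_metrics`: `track_id`, `frame`,
#'   `time_min`, `label`, `area_px2`, `skeleton_len_px`, `roundness`,
#'   `load_au`.
#' @export
measure_tracks <- function(tracks, labels, fluor = NULL, frame_interval = 15,
                           compute_length = TRUE) {
  frames <- sort(unique(tracks$frame))
  per_frame <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    f <- frames[k]
    lab <- labels[[f + 1L]]
    rows <- tracks[tracks$frame == f, , drop = FALSE]
    if (nrow(rows) == 0L) next
    rt <- region_table(lab)
    loads <- rep(NA_real_, max(lab))
    if (!is.null(fluor)) {
      fl <- fluor[[f + 1L]]
      sel <- lab > 0L
      if (any(sel)) {
        agg <- rowsum(fl[sel], lab[sel])
        loads[as.integer(rownames(agg))] <- agg[, 1]
      }
      loads[is.na(loads)] <- 0
    }
    skel <- rep(NA_real_, max(lab))
    if (compute_length) {
      for (i in rows$label) {
        sub <- crop_label(lab, rt, i)
        skel[i] <- skeleton_length(skeletonize_mask(sub))
      }
    }
    per_frame[[k]] <- data.frame(
      track_id = rows$track_id, frame = f, time_min = f * frame_interval,
      label = rows$label,
      area_px2 = rt$area_px2[rows$label],
      skeleton_len_px = skel[rows$label],
      roundness = rt$roundness[rows$label],
      load_au = loads[rows$label])
  }
  out <- do.call(rbind, per_frame[!vapply(per_frame, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(track_id = integer(0), frame = integer(0),
                      time_min = numeric(0), label = integer(0),
                      area_px2 = numeric(0), skeleton_len_px = numeric(0),
                      roundness = numeric(0), load_au = numeric(0))
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("track_metrics", "data.frame")
  out
}

crop_label <- function(lab, rt, i) {
  lab[max(1L, rt$bbox_y0[i] - 1L):min(nrow(lab), rt$bbox_y1[i] + 1L),
      max(1L, rt$bbox_x0[i] - 1L):min(ncol(lab), rt$bbox_x1[i] + 1L),
      drop = FALSE] == i
}

#' Call germination from a projected-area trace
#'
#' A spore is germinating when its projected area (volume proxy) reaches
#' `fold_threshold` times the initial area within the first `window` minutes
#' of the track (default: 1.5-fold within 10 h). If the trace ends before the
#' window is covered and the threshold has not been reached, the call is
#' undetermined (`NA`).
#'
#' @param area numeric area series (pixels^2), first element = initial area.
#' @param time_min time of each point in minutes from the start of the track.
#' @param params a [germination_params()].
#' @return `TRUE`, `FALSE`, or `NA` (undetermined, right-censored).
#' @export
call_germination <- function(area, time_min, params = germination_params()) {
  stopifnot(length(area) == length(time_min), length(area) >= 1L)
  o <- order(time_min)
  area <- area[o]; time_min <- time_min[o]
  if (is.na(area[1]) || area[1] <= 0)
    stop("initial area must be positive", call. = FALSE)
  rel_t <- time_min - time_min[1]
  win <- rel_t <= params$window
  if (any(area[win] >= params$fold_threshold * area[1], na.rm = TRUE))
    return(TRUE)
  if (max(rel_t) < params$window) return(NA)
  FALSE
}

#' Doubling time from an exponential fit
#'
#' Least-squares fit of `ln(size)` against time over the growth phase and
#' conversion of the slope to a doubling time, `T_D = ln(2) / slope`. The
#' growth phase starts at the first point reaching `from_fold` times the
#' initial size (set `from_fold = NULL` to use the whole series); this skips
#' the pre-germination lag, during which the area is flat.
#'
#' @param time_min time in minutes.
#' @param size positive sizes (area, voxels, ...).
#' @param from_fold growth-phase entry threshold (default 1.5), or `NULL`.
#' @param min_points minimum number of fit points (default 3).
#' @return doubling time in minutes, or `NA` if the growth phase is too short
#'   or the fitted slope is not positive.
#' @examples
#' t <- seq(0, 480, 15)
#' fit_doubling_time(t, 100 * 2^(t / 98), from_fold = NULL)  # 98
#' @export
fit_doubling_time <- function(time_min, size, from_fold = 1.5, min_points = 3L) {
  stopifnot(length(time_min) == length(size))
  ok <- !is.na(size) & !is.na(time_min)
  time_min <- time_min[ok]; size <- size[ok]
  if (any(size <= 0)) stop("sizes must be positive", call. = FALSE)
  o <- order(time_min)
  time_min <- time_min[o]; size <- size[o]
  if (!is.null(from_fold)) {
    i0 <- which(size >= from_fold * size[1])[1]
    if (is.na(i0)) return(NA_real_)
    time_min <- time_min[i0:length(time_min)]
    size <- size[i0:length(size)]
  }
  if (length(size) < min_points) return(NA_real_)
  slope <- stats::coef(stats::lm.fit(cbind(1, time_min), log(size)))[2]
  if (!is.finite(slope) || slope <= 0) return(NA_real_)
  unname(log(2) / slope)
}

#' Doubling time in the maximum-growth window
#'
#' Fits `ln(size)` against time in every sliding window of `window` points and
#' returns the doubling time of the window with the maximal slope (T_Dmax).
#' For a series with a lag followed by exponential growth this excludes the
#' lag and recovers the exponential-phase doubling time.
#'
#' @param time_min time in minutes.
#' @param size positive sizes.
#' @param window window length in points (default 5).
#' @return list with `t_dmax_min` (minutes, `NA` if no window has a positive
#'   slope), `window_start_min`, `slope_per_min`.
#' @export
max_growth_doubling_time <- function(time_min, size, window = 5L) {
  stopifnot(length(time_min) == length(size), window >= 2L)
  if (length(size) < window)
    stop("series shorter than the window", call. = FALSE)
  if (any(is.na(size)) || any(size <= 0))
    stop("sizes must be positive and complete", call. = FALSE)
  o <- order(time_min)
  time_min <- time_min[o]; size <- size[o]
  n <- length(size)
  best <- list(t_dmax_min = NA_real_, window_start_min = NA_real_,
               slope_per_min = -Inf)
  for (i in seq_len(n - window + 1L)) {
    j <- i:(i + window - 1L)
    slope <- stats::coef(stats::lm.fit(cbind(1, time_min[j]), log(size[j])))[2]
    if (is.finite(slope) && slope > best$slope_per_min) {
      best <- list(t_dmax_min = if (slope > 0) log(2) / slope else NA_real_,
                   window_start_min = time_min[i],
                   slope_per_min = unname(slope))
    }
  }
  best$t_dmax_min <- unname(best$t_dmax_min)
  best
}

#' Bacterial load at the start of a track
#'
#' The summed fluorescence (z sum-projection over the object mask) at the
#' first frame of the track -- the per-spore bacterial load at the beginning
#' of the imaging experiment.
#'
#' @param metrics a [measure_tracks()] result (or any data.frame with
#'   `track_id`, `frame`, `load_au`).
#' @return data.frame: `track_id`, `load_t0_au`.
#' @export
load_at_start <- function(metrics) {
  sp <- split(metrics, metrics$track_id)
  data.frame(track_id = as.integer(names(sp)),
             load_t0_au = vapply(sp, function(d) {
               d$load_au[which.min(d$frame)]
             }, numeric(1)), row.names = NULL)
}

#' Per-track germination and growth summary
#'
#' Applies [call_germination()], [fit_doubling_time()] and
#' [max_growth_doubling_time()] to every track.
#'
#' @param metrics a [measure_tracks()] result.
#' @param germ a [germination_params()].
#' @param tdmax_window window (points) for T_Dmax; `NA` skips tracks shorter
#'   than the window.
#' @return data.frame of class `spore_summary`: `track_id`, `birth_frame`,
#'   `n_frames`, `germinating`, `t_d_min`, `t_dmax_min`, `load_t0_au`.
#' @export
summarize_tracks <- function(metrics, germ = germination_params(),
                             tdmax_window = 5L) {
  sp <- split(metrics, metrics$track_id)
  rows <- lapply(sp, function(d) {
    d <- d[order(d$frame), , drop = FALSE]
    g <- tryCatch(call_germination(d$area_px2, d$time_min, germ),
                  error = function(e) NA)
    td <- if (isTRUE(g)) fit_doubling_time(d$time_min, d$area_px2,
                                           from_fold = germ$fold_threshold)
          else NA_real_
    tdm <- if (nrow(d) >= tdmax_window && all(d$area_px2 > 0))
      max_growth_doubling_time(d$time_min, d$area_px2, tdmax_window)$t_dmax_min
    else NA_real_
    data.frame(track_id = d$track_id[1], birth_frame = d$frame[1],
               n_frames = nrow(d), germinating = g, t_d_min = td,
               t_dmax_min = tdm,
               load_t0_au = d$load_au[1])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("spore_summary", "data.frame")
  out
}
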