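# Rendering of synthetic spores: discs plus axis-aligned rectangular germ
# tubes. The simple geometry has closed-form area/perimeter, which gives
# analytic roundness oracles for the segmentation filter.

clip01 <- function(x) {
  # keeps dim attributes, unlike pmax/pmin with a scalar first argument
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

blur_mat <- function(x, sigma) {
  if (sigma <= 0) return(x)
  as.matrix(EBImage::imageData(EBImage::gblur(x, sigma = sigma)))
}

# draw a filled disc into `img` (any value), returns modified img
draw_disc <- function(img, cy, cx, r, value) {
  y0 <- max(1L, floor(cy - r)); y1 <- min(nrow(img), ceiling(cy + r))
  x0 <- max(1L, floor(cx - r)); x1 <- min(ncol(img), ceiling(cx + r))
  if (y0 > y1 || x0 > x1) return(img)
  ys <- y0:y1; xs <- x0:x1
  dy2 <- (ys - cy)^2
  dx2 <- (xs - cx)^2
  hit <- outer(dy2, dx2, "+") <= r^2
  sub <- img[ys, xs, drop = FALSE]
  sub[hit] <- value
  img[ys, xs] <- sub
  img
}

draw_rect <- function(img, y0, y1, x0, x1, value) {
  ys <- max(1L, round(y0)):min(nrow(img), round(y1))
  xs <- max(1L, round(x0)):min(ncol(img), round(x1))
  if (length(ys) < 1L || length(xs) < 1L) return(img)
  img[ys, xs] <- value
  img
}

# per-spore rendered geometry at one frame: disc radius and tube extent
spore_geometry <- function(pop, config, frame) {
  t_min <- frame * config$frame_interval
  a0 <- pi * pop$radius_px^2
  a_true <- truth_area_series(pop, frames = frame)[, 1]
  a <- pmin(a_true, a0 * config$max_render_fold)
  jit <- attr(pop, "area_jitter")
  if (config$area_jitter_sd > 0 && frame < ncol(jit))
    a <- a * exp(jit[, frame + 1L])
  w <- config$germ_tube_width
  frames_since_lag <- pmax(0, (t_min - pop$lag_min) / config$frame_interval)
  tube <- ifelse(pop$germinating & t_min > pop$lag_min,
                 pmin(config$germ_tube_rate * frames_since_lag,
                      config$germ_tube_max_len,
                      pmax(0, 0.3 * (a - a0) / w)),
                 0)
  r <- sqrt(pmax(a - w * tube, 0.25 * a0) / pi)
  data.frame(spore_id = pop$spore_id, cy = pop$center_y, cx = pop$center_x,
             r = r, tube = tube, dir = pop$tube_dir, half_w = w / 2)
}

# label + body-label masks of one frame; later spores overwrite earlier ones
# where footprints overlap
render_frame_masks <- function(pop, config, frame) {
  ny <- config$image_shape[1]; nx <- config$image_shape[2]
  labels <- matrix(0L, ny, nx)
  body <- matrix(0L, ny, nx)
  if (nrow(pop) == 0L) return(list(labels = labels, body = body))
  g <- spore_geometry(pop, config, frame)
  clipped <- FALSE
  for (i in seq_len(nrow(g))) {
    if (g$cy[i] - g$r[i] < 1 || g$cy[i] + g$r[i] > ny ||
        g$cx[i] - g$r[i] < 1 || g$cx[i] + g$r[i] > nx) clipped <- TRUE
    labels <- draw_disc(labels, g$cy[i], g$cx[i], g$r[i], g$spore_id[i])
    body <- draw_disc(body, g$cy[i], g$cx[i], g$r[i], g$spore_id[i])
    if (g$tube[i] >= 1) {
      e <- tube_extent(g$cy[i], g$cx[i], g$r[i], g$tube[i], g$half_w[i], g$dir[i])
      if (e$y1 < 1 || e$y0 > ny || e$x1 < 1 || e$x0 > nx ||
          e$y0 < 1 || e$y1 > ny || e$x0 < 1 || e$x1 > nx) clipped <- TRUE
      labels <- draw_rect(labels, e$y0, e$y1, e$x0, e$x1, g$spore_id[i])
    }
  }
  if (clipped)
    warning("spore footprint clipped at the frame boundary", call. = FALSE)
  list(labels = labels, body = body)
}

tube_extent <- function(cy, cx, r, len, half_w, dir) {
  # dir: 1 +y, 2 +x, 3 -y, 4 -x; tube starts just inside the disc edge
  s <- r - 1
  switch(dir,
         list(y0 = cy + s, y1 = cy + s + len, x0 = cx - half_w, x1 = cx + half_w),
         list(y0 = cy - half_w, y1 = cy + half_w, x0 = cx + s, x1 = cx + s + len),
         list(y0 = cy - s - len, y1 = cy - s, x0 = cx - half_w, x1 = cx + half_w),
         list(y0 = cy - half_w, y1 = cy + half_w, x0 = cx - s - len, x1 = cx - s))
}

#' Render per-frame ground-truth label masks
#'
#' @param pop a [generate_population()] result.
#' @param frames 0-based frame indices (default all).
#' @return a list with one element per frame, each `list(labels, body)`:
#'   integer label matrices of the full footprint (body + germ tube) and of
#'   the spore body alone.
#' @export
render_truth_masks <- function(pop, frames = NULL) {
  config <- attr(pop, "config")
  if (is.null(frames)) frames <- seq_len(config$n_frames) - 1L
  lapply(frames, function(f) render_frame_masks(pop, config, f))
}

#' Render a synthetic two-channel time-lapse stack
#'
#' Renders the population as a widefield-like channel (dark background, bright
#' spores, replicated over z) and a fluorescence channel in which the spore's
#' true bacterial load is spread uniformly over its footprint in the middle
#' z-slice, so that the z sum-projection integrated over the spore mask equals
#' the true load exactly when noise is off. Noise is applied last: additive
#' Gaussian (sd `noise_model$gaussian_sd` on each channel's 0-1 scale; for the
#' fluorescence channel the scale is its per-frame maximum) and optional
#' Poisson resampling of fluorescence counts.
#'
#' @param pop a [generate_population()] result.
#' @param frames 0-based frame indices (default all).
#' @return object of class `spore_stack`: list with `widefield` and `fluor`
#'   (numeric arrays T x Z x Y x X), `labels` and `body` (integer arrays
#'   T x Y x X), `frames`, `frame_interval`, `config`.
#' @export
render_timelapse <- function(pop, frames = NULL) {
  config <- attr(pop, "config")
  if (is.null(frames)) frames <- seq_len(config$n_frames) - 1L
  nt <- length(frames); nz <- config$n_z
  ny <- config$image_shape[1]; nx <- config$image_shape[2]
  wf <- array(0.1, dim = c(nt, nz, ny, nx))
  fl <- array(0, dim = c(nt, nz, ny, nx))
  lab <- array(0L, dim = c(nt, ny, nx))
  bod <- array(0L, dim = c(nt, ny, nx))
  loads <- truth_load_series(pop, frames = frames)
  zmid <- (nz + 1L) %/% 2L
  for (k in seq_len(nt)) {
    mk <- render_frame_masks(pop, attr(pop, "config"), frames[k])
    lab[k, , ] <- mk$labels
    bod[k, , ] <- mk$body
    wfk <- matrix(0.1, ny, nx)
    wfk[mk$labels > 0] <- 0.6
    flk <- matrix(0, ny, nx)
    if (nrow(pop) > 0L) {
      npix <- tabulate(mk$labels[mk$labels > 0L], nbins = nrow(pop))
      present <- which(npix > 0L)
      for (i in present) {
        flk[mk$labels == i] <- loads[i, k] / npix[i]
      }
    }
    if (config$noise_model$poisson) {
      flk[] <- stats::rpois(length(flk), pmax(0, flk))
    }
    sdg <- config$noise_model$gaussian_sd
    for (z in seq_len(nz)) {
      w <- wfk
      f <- if (z == zmid) flk else matrix(0, ny, nx)
      if (sdg > 0) {
        w <- w + stats::rnorm(length(w), 0, sdg)
        fscale <- max(f)
        if (fscale > 0) {
          f <- f + stats::rnorm(length(f), 0, sdg * fscale)
          f[f < 0] <- 0
        }
      }
      wf[k, z, , ] <- clip01(w)
      fl[k, z, , ] <- f
    }
  }
  structure(list(widefield = wf, fluor = fl, labels = lab, body = bod,
                 frames = frames, frame_interval = config$frame_interval,
                 config = config),
            class = "spore_stack")
}

#' @export
print.spore_stack <- function(x, ...) {
  d <- dim(x$widefield)
  cat(sprintf("spore_stack: T=%d Z=%d %dx%d px, 2 channels, dt=%g min\n",
              d[1], d[2], d[3], d[4], x$frame_interval))
  invisible(x)
}

#' Sum-projection of the fluorescence channel over z
#'
#' @param stack a `spore_stack` (or any T x Z x Y x X array).
#' @return list of Y x X matrices, one per frame.
#' @export
fluor_projection <- function(stack) {
  arr <- if (inherits(stack, "spore_stack")) stack$fluor else stack
  lapply(seq_len(dim(arr)[1]), function(k) {
    m <- arr[k, , , , drop = FALSE]
    apply(array(m, dim = dim(arr)[2:4]), c(2, 3), sum)
  })
}

#' Simulate backend probability maps from truth masks
#'
#' Stands in for the three segmentation models whose outputs the integration
#' stage consumes: a whole-cell map (union of footprints), a contour map with
#' ridges along object boundaries -- including the shared ridge between
#' touching spores -- and a spore-body map that excludes germ tubes. With zero
#' corruption the maps are exact binary images of the truth.
#'
#' @param masks one frame from [render_truth_masks()] (`list(labels, body)`),
#'   or a list of such frames.
#' @param corruption a [map_corruption()].
#' @return object of class `probability_maps` (`list(cell, contour, body)`,
#'   matrices in \[0, 1\]), or a list of them for multi-frame input.
#' @export
simulate_probability_maps <- function(masks, corruption = map_corruption()) {
  stopifnot(inherits(corruption, "map_corruption"))
  if (!is.list(masks)) stop("masks must be list(labels, body) or a list of frames", call. = FALSE)
  if (is.null(masks$labels)) {
    return(lapply(masks, simulate_probability_maps, corruption = corruption))
  }
  lab <- masks$labels
  body_lab <- if (is.null(masks$body)) lab else masks$body
  fg <- lab > 0L
  ridge <- fg & (lab != nb(lab, 1L, 0L, 0L) | lab != nb(lab, -1L, 0L, 0L) |
                 lab != nb(lab, 0L, 1L, 0L) | lab != nb(lab, 0L, -1L, 0L))
  if (corruption$contour_dilation > 0L) {
    for (i in seq_len(corruption$contour_dilation)) {
      ridge <- ridge | nb(ridge, 1L, 0L) | nb(ridge, -1L, 0L) |
        nb(ridge, 0L, 1L) | nb(ridge, 0L, -1L)
    }
  }
  cell <- blur_mat(fg * 1, corruption$blur_sigma)
  contour <- blur_mat(ridge * 1, corruption$contour_blur_sigma)
  body <- blur_mat((body_lab > 0L) * 1, corruption$blur_sigma)
  if (corruption$noise_sd > 0) {
    cell <- cell + stats::rnorm(length(cell), 0, corruption$noise_sd)
    contour <- contour + stats::rnorm(length(contour), 0, corruption$noise_sd)
    body <- body + stats::rnorm(length(body), 0, corruption$noise_sd)
  }
  structure(list(cell = clip01(cell), contour = clip01(contour),
                 body = clip01(body)),
            class = "probability_maps")
}
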