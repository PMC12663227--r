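#' Label connected components of a binary mask
#'
#' 4- or 8-connected component labeling. Labeling is delegated to
#' `EBImage::bwlabel()` (4-connected); for 8-connectivity, 4-connected labels
#' that touch diagonally are merged with a union-find pass over the label
#' adjacency graph.
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 4 or 8.
#' @return integer label matrix, background 0, labels 1..k.
#' @export
label_components <- function(mask, connectivity = 8L) {
  m <- mask != 0
  lab <- matrix(as.integer(EBImage::imageData(EBImage::bwlabel(m * 1))),
                nrow(m), ncol(m))
  if (connectivity == 8L && max(lab) > 1L) {
    pairs <- rbind(diag_pairs(lab, 1L, 1L), diag_pairs(lab, 1L, -1L))
    if (nrow(pairs) > 0L) {
      parent <- seq_len(max(lab))
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      for (r in seq_len(nrow(pairs))) {
        a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
      root <- vapply(seq_along(parent), find, integer(1))
      lab[lab > 0L] <- root[lab[lab > 0L]]
    }
  }
  relabel_contiguous(lab)
}

diag_pairs <- function(lab, dy, dx) {
  nbr <- nb(lab, dy, dx, 0L)
  sel <- lab > 0L & nbr > 0L & lab != nbr
  unique(cbind(lab[sel], nbr[sel]))
}

relabel_contiguous <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) == 0L) return(lab)
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  lab[lab > 0L] <- map[lab[lab > 0L]]
  lab
}

#' Integrate whole-cell, contour and body probability maps into spore labels
#'
#' The contour map separates touching spores and the body map confirms that
#' segmented objects are connected to a cell body: (i) the cell map is
#' binarized; (ii) binarized contour pixels are subtracted so that touching
#' objects fall apart at the shared ridge; (iii) remaining pixels are labeled
#' as connected components; (iv) the subtracted cell pixels are reassigned to
#' the adjacent component with the largest shared border (ties to the lower
#' label id) so object areas are not biased by the ridge width; (v) components
#' with no overlap with the binarized body map are discarded; (vi) components
#' below `min_area` are discarded. Labels are relabeled contiguously.
#'
#' The roundness filter is applied separately by [filter_objects()].
#'
#' @param maps a `probability_maps` object (see [simulate_probability_maps()]
#'   for the contract) or `list(cell, contour, body)` of equal-shaped matrices.
#' @param params a [segmentation_params()].
#' @return integer label matrix.
#' @examples
#' masks <- list(labels = disc_mask(c(64, 64), c(32, 32), 10) * 1L)
#' maps <- simulate_probability_maps(masks, map_corruption(0, 0, 0))
#' max(integrate_maps(maps, segmentation_params()))  # 1 object
#' @export
integrate_maps <- function(maps, params = segmentation_params()) {
  stopifnot(inherits(params, "segmentation_params"))
  if (is.null(maps$cell) || is.null(maps$contour) || is.null(maps$body))
    stop("maps must contain cell, contour and body", call. = FALSE)
  if (!all(dim(maps$cell) == dim(maps$contour)) ||
      !all(dim(maps$cell) == dim(maps$body)))
    stop("probability maps must share one shape", call. = FALSE)

  cell <- maps$cell >= params$cell_threshold
  # strict inequality: contour_threshold = 1 disables splitting entirely,
  # which merges touching objects back into one component
  contour <- maps$contour > params$contour_threshold
  body <- maps$body >= params$body_threshold

  seed <- cell & !contour
  lab <- label_components(seed, params$connectivity)
  lab <- reassign_ridge_pixels(lab, cell, params$connectivity)

  if (max(lab) > 0L) {
    # (v) body-overlap check, (vi) size floor
    n <- max(lab)
    in_body <- tabulate(lab[body & lab > 0L], nbins = n)
    area <- tabulate(lab[lab > 0L], nbins = n)
    drop <- in_body == 0L | area < params$min_area
    if (any(drop)) lab[lab %in% which(drop)] <- 0L
  }
  relabel_contiguous(lab)
}

# grow labels into cell-positive, still-unlabeled pixels (the subtracted
# contour ridge); each pixel joins the neighboring component with the most
# adjacent pixels, ties broken toward the lower label id
reassign_ridge_pixels <- function(lab, cell, connectivity = 8L) {
  shifts <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  if (connectivity == 8L)
    shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L)))
  repeat {
    todo <- which(cell & lab == 0L)
    if (length(todo) == 0L) break
    nbmat <- vapply(shifts, function(s) nb(lab, s[1], s[2], 0L)[todo],
                    integer(length(todo)))
    if (length(todo) == 1L) nbmat <- matrix(nbmat, nrow = 1L)
    k <- ncol(nbmat)
    best_lab <- integer(length(todo))
    best_score <- rep(-Inf, length(todo))
    for (j in seq_len(k)) {
      cand <- nbmat[, j]
      cnt <- rowSums(nbmat == cand) * (cand > 0L)
      score <- ifelse(cand > 0L, cnt - cand / (max(lab) + 1), -Inf)
      better <- score > best_score
      best_lab[better] <- cand[better]
      best_score[better] <- score[better]
    }
    assignable <- best_lab > 0L
    if (!any(assignable)) break  # isolated ridge pixels with no labeled neighbor
    lab[todo[assignable]] <- best_lab[assignable]
  }
  lab
}

#' Region table of a label image
#'
#' Per-object measurements: area (pixel count), perimeter
#' ([mask_perimeter()]), roundness ([mask_roundness()]), centroid and bounding
#' box. Coordinates are pixel-based, 1-based, y before x.
#'
#' @param lab integer label matrix.
#' @return data.frame with one row per label.
#' @export
region_table <- function(lab) {
  n <- max(lab)
  if (n == 0L)
    return(data.frame(label = integer(0), area_px2 = numeric(0),
                      perimeter_px = numeric(0), roundness = numeric(0),
                      centroid_y = numeric(0), centroid_x = numeric(0),
                      bbox_y0 = integer(0), bbox_y1 = integer(0),
                      bbox_x0 = integer(0), bbox_x1 = integer(0)))
  idx <- which(lab > 0L)
  ids <- lab[idx]
  ys <- (idx - 1L) %% nrow(lab) + 1L
  xs <- (idx - 1L) %/% nrow(lab) + 1L
  fid <- factor(ids, levels = seq_len(n))  # labels may be non-contiguous
  area <- tabulate(ids, nbins = n)
  cy <- as.numeric(tapply(ys, fid, mean))
  cx <- as.numeric(tapply(xs, fid, mean))
  y0 <- as.integer(tapply(ys, fid, min)); y1 <- as.integer(tapply(ys, fid, max))
  x0 <- as.integer(tapply(xs, fid, min)); x1 <- as.integer(tapply(xs, fid, max))
  per <- rep(NA_real_, n); rnd <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (area[i] == 0L) next
    # measure on a padded crop so boundary configurations are complete
    sub <- lab[max(1L, y0[i] - 1L):min(nrow(lab), y1[i] + 1L),
               max(1L, x0[i] - 1L):min(ncol(lab), x1[i] + 1L), drop = FALSE] == i
    per[i] <- mask_perimeter(sub)
    rnd[i] <- if (per[i] > 0) 4 * pi * area[i] / per[i]^2 else NA_real_
  }
  data.frame(label = seq_len(n), area_px2 = area, perimeter_px = per,
             roundness = rnd, centroid_y = cy, centroid_x = cx,
             bbox_y0 = y0, bbox_y1 = y1, bbox_x0 = x0, bbox_x1 = x1)
}

#' Filter labeled objects by roundness and size
#'
#' Retains objects with `roundness >= min_roundness` (degenerate objects with
#' undefined roundness are removed) and `area >= min_area`, then relabels
#' contiguously. The removed original label ids are attached as attribute
#' `"removed"`. Filtering out elongated objects ensures that only early
#' germinating spores are carried through tracking and growth quantification.
#'
#' @param lab integer label matrix.
#' @param params a [segmentation_params()].
#' @return filtered integer label matrix with attribute `removed`.
#' @export
filter_objects <- function(lab, params = segmentation_params()) {
  rt <- region_table(lab)
  if (nrow(rt) == 0L) {
    attr(lab, "removed") <- integer(0)
    return(lab)
  }
  keep <- !is.na(rt$roundness) & rt$roundness >= params$min_roundness &
    rt$area_px2 >= params$min_area
  removed <- rt$label[!keep]
  if (length(removed) > 0L) lab[lab %in% removed] <- 0L
  out <- relabel_contiguous(lab)
  attr(out, "removed") <- removed
  out
}
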