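#' Match labeled objects between consecutive frames by modal spatial overlap
#'
#' For each object at frame t+1, the histogram of frame-t labels over its
#' pixels is computed and the object is assigned to the modal non-background
#' frame-t label (background is excluded from the mode, so an object mostly
#' over background but partly over one frame-t object is still assigned to
#' it). Modal ties are broken toward the lower frame-t label id. An object
#' with zero overlap with any frame-t object is marked new (`NA`).
#'
#' @param labels_t,labels_t1 integer label matrices of the same shape.
#' @return data.frame of class `frame_match`: `label_t1`, `label_t` (`NA` =
#'   new), `overlap` (pixel count of the modal pair).
#' @export
match_frames <- function(labels_t, labels_t1) {
  if (!all(dim(labels_t) == dim(labels_t1)))
    stop("label images must share one shape", call. = FALSE)
  n1 <- max(labels_t1)
  out <- data.frame(label_t1 = seq_len(n1),
                    label_t = rep(NA_integer_, n1),
                    overlap = rep(0L, n1))
  if (n1 == 0L) {
    class(out) <- c("frame_match", "data.frame")
    return(out)
  }
  sel <- labels_t1 > 0L & labels_t > 0L
  if (any(sel)) {
    a <- labels_t1[sel]
    b <- labels_t[sel]
    key <- (a - 1) * (max(labels_t) + 1) + b
    tab <- table(key)
    kv <- as.numeric(names(tab))
    cnt <- as.integer(tab)
    pa <- floor(kv / (max(labels_t) + 1)) + 1
    pb <- kv - (pa - 1) * (max(labels_t) + 1)
    # per t+1 label: max count, ties to lower t label id
    ord <- order(pa, -cnt, pb)
    first <- !duplicated(pa[ord])
    hit <- ord[first]
    out$label_t[pa[hit]] <- as.integer(pb[hit])
    out$overlap[pa[hit]] <- cnt[hit]
  }
  class(out) <- c("frame_match", "data.frame")
  out
}

#' Assemble spore tracks across a label-image sequence
#'
#' Chains [match_frames()] results over a sequence of label images. Every
#' labeled object in every frame belongs to exactly one track. When two
#' frame-t+1 objects claim the same frame-t ancestor, the one with the larger
#' overlap continues the track (ties to the lower t+1 label id) and the other
#' starts a new track; a frame-t object claimed by nobody has its track closed
#' at t. No gap closing is performed: a vanished object is never re-linked.
#'
#' @param labels list of integer label matrices, one per frame (>= 1 frame).
#' @param frames optional 0-based frame indices (default `0..length-1`).
#' @return data.frame of class `track_table`: `track_id`, `frame`, `label`,
#'   ordered by track then frame; per-track birth/death are available via
#'   [track_summary()].
#' @export
build_tracks <- function(labels, frames = NULL) {
  stopifnot(is.list(labels), length(labels) >= 1L)
  if (is.null(frames)) frames <- seq_along(labels) - 1L
  next_id <- 1L
  active <- integer(0)  # active[label at current frame] -> track_id
  rows <- vector("list", length(labels))
  n0 <- max(labels[[1]])
  active <- if (n0 > 0L) seq_len(n0) else integer(0)
  next_id <- n0 + 1L
  rows[[1]] <- if (n0 > 0L)
    data.frame(track_id = active, frame = frames[1], label = seq_len(n0))
  for (k in seq_along(labels)[-1]) {
    fm <- match_frames(labels[[k - 1L]], labels[[k]])
    n1 <- nrow(fm)
    ids <- integer(n1)
    if (n1 > 0L) {
      # resolve conflicts: larger overlap continues, ties to lower t+1 label
      ord <- order(fm$label_t, -fm$overlap, fm$label_t1, na.last = TRUE)
      continues <- !is.na(fm$label_t[ord]) & !duplicated(fm$label_t[ord], incomparables = NA)
      winner <- logical(n1)
      winner[ord] <- continues
      for (j in seq_len(n1)) {
        if (winner[j]) {
          ids[j] <- active[fm$label_t[j]]
        } else {
          ids[j] <- next_id
          next_id <- next_id + 1L
        }
      }
    }
    active <- ids
    rows[[k]] <- if (n1 > 0L)
      data.frame(track_id = ids, frame = frames[k], label = seq_len(n1))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(track_id = integer(0), frame = integer(0), label = integer(0))
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("track_table", "data.frame")
  out
}

#' Per-track birth and death frames
#'
#' @param tracks a [build_tracks()] result.
#' @param last_frame 0-based index of the last analyzed frame; a track whose
#'   final assignment is at `last_frame` is open (right-censored),
#'   `death_frame` is `NA`.
#' @return data.frame: `track_id`, `birth_frame`, `death_frame`, `n_frames`.
#' @export
track_summary <- function(tracks, last_frame = max(tracks$frame)) {
  if (nrow(tracks) == 0L)
    return(data.frame(track_id = integer(0), birth_frame = integer(0),
                      death_frame = integer(0), n_frames = integer(0)))
  sp <- split(tracks$frame, tracks$track_id)
  data.frame(track_id = as.integer(names(sp)),
             birth_frame = vapply(sp, min, numeric(1)),
             death_frame = ifelse(vapply(sp, max, numeric(1)) >= last_frame,
                                  NA_integer_, vapply(sp, max, numeric(1))),
             n_frames = lengths(sp), row.names = NULL)
}
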