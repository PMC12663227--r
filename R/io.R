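#' Write a time-lapse stack as multi-page TIFF with a JSON sidecar
#'
#' Pages are written in T-major, then Z, then C (widefield, fluorescence)
#' order as 16-bit grayscale; per-channel scale factors and the axis layout
#' are recorded in a `<path>.json` sidecar together with the frame interval
#' and the seed. Intensities are quantized to 16-bit on write, so a
#' write-read-write cycle is byte-identical.
#'
#' @param stack a `spore_stack` from [render_timelapse()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "spore_stack"))
  d <- dim(stack$widefield)  # T Z Y X
  fl_scale <- max(stack$fluor, 1e-12)
  pages <- vector("list", d[1] * d[2] * 2L)
  i <- 0L
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) {
    pages[[i + 1L]] <- quant16(clip01(stack$widefield[t, z, , ]))
    pages[[i + 2L]] <- quant16(stack$fluor[t, z, , ] / fl_scale)
    i <- i + 2L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(axes = "TZCYX",
               dims = list(T = d[1], Z = d[2], C = 2L, Y = d[3], X = d[4]),
               channels = c("widefield", "fluor"),
               fluor_scale = fl_scale,
               frame_interval_min = stack$frame_interval,
               frames = stack$frames,
               seed = stack$config$seed,
               config_hash = config_hash(stack$config),
               sporetrack_version = as.character(utils::packageVersion("sporetrack")))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

quant16 <- function(m) round(clip01(m) * 65535) / 65535

sidecar_path <- function(path) paste0(path, ".json")

config_hash <- function(config) {
  # order-stable digest of the config without external dependencies
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  sum(utf8ToInt(as.character(s)) * (seq_len(nchar(s)) %% 251 + 1)) %% 2147483647
}

#' Read a time-lapse stack written by [write_stack()]
#'
#' Axes are restored from the JSON sidecar. Without a sidecar, only an
#' unambiguous single 2-D page is accepted (promoted to T=1, Z=1 with a
#' warning, requiring an explicit `frame_interval`); a multi-page file
#' without metadata is an error -- the axis order is never guessed.
#'
#' @param path TIFF path.
#' @param frame_interval frame interval in minutes, required when the sidecar
#'   is absent.
#' @return a `spore_stack` (without truth labels).
#' @export
read_stack <- function(path, frame_interval = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    if (length(pages) == 1L) {
      if (is.null(frame_interval))
        stop("no sidecar metadata: frame_interval must be given ",
             "(CLI: --frame-interval)", call. = FALSE)
      warning("single 2-D image promoted to T=1, Z=1", call. = FALSE)
      p <- pages[[1]]
      wf <- array(p, dim = c(1, 1, nrow(p), ncol(p)))
      return(structure(list(widefield = wf,
                            fluor = array(0, dim = dim(wf)),
                            frames = 0L, frame_interval = frame_interval,
                            config = NULL),
                       class = "spore_stack"))
    }
    stop("multi-page TIFF without sidecar metadata: unknown axis order",
         call. = FALSE)
  }
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (!identical(meta$axes, "TZCYX"))
    stop("unsupported axis order in sidecar: ", meta$axes, call. = FALSE)
  d <- meta$dims
  wf <- array(0, dim = c(d[["T"]], d[["Z"]], d[["Y"]], d[["X"]]))
  fl <- wf
  i <- 0L
  for (t in seq_len(d[["T"]])) for (z in seq_len(d[["Z"]])) {
    wf[t, z, , ] <- pages[[i + 1L]]
    fl[t, z, , ] <- pages[[i + 2L]] * meta$fluor_scale
    i <- i + 2L
  }
  structure(list(widefield = wf, fluor = fl, frames = meta$frames,
                 frame_interval = meta$frame_interval_min,
                 config = NULL, meta = meta),
            class = "spore_stack")
}

#' Write a label image (or list of them) as 16-bit label TIFF
#'
#' @param labels integer label matrix or list of matrices.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  if (!is.list(labels)) labels <- list(labels)
  pages <- lapply(labels, function(m) m / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  out <- lapply(pages, function(p) {
    matrix(as.integer(round(p * 65535)), nrow(p), ncol(p))
  })
  if (length(out) == 1L) out[[1]] else out
}

# CSV with a commented provenance header; read back with read_result_csv()
write_result_csv <- function(df, path, seed = NA, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# sporetrack %s", as.character(utils::packageVersion("sporetrack"))),
    sprintf("# seed: %s", seed),
    sprintf("# config_hash: %s",
            if (is.null(config)) NA else config_hash(config)),
    "# coordinates: pixels, origin top-left, y before x, 1-based; frames 0-based; times in minutes"),
    con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a sporetrack result CSV (skipping provenance comments)
#'
#' @param path CSV path written by the pipeline.
#' @return data.frame.
#' @export
read_result_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
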