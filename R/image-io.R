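#' Time-lapse stack container
#'
#' One dye's acquisition: a `height x width x T` grid of camera counts on a
#' uniform time base. Counts are integers in `[0, 2^bit_depth - 1]`; the
#' camera here delivers a 14-bit payload carried in a 16-bit container.
#'
#' @param frames Numeric or integer array, `height x width x T` with
#'   `T >= 2`.
#' @param frame_interval_s Seconds between consecutive frames.
#' @param dye_label Dye identifier, typically `"FU"` or `"TR"`.
#' @param bit_depth Payload bit depth; default 14.
#' @param source Optional path or identifier of origin.
#' @param meta Optional named list of extra metadata (ground truth for
#'   phantoms, geometry, ...).
#'
#' @return A `timelapse` object.
#' @export
timelapse <- function(frames, frame_interval_s, dye_label = "FU",
                      bit_depth = 14L, source = NULL, meta = list()) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop_difcanal("`frames` must be a height x width x T array",
                  "invalid_input")
  }
  if (dim(frames)[3] < 2L) {
    stop_difcanal("a time lapse needs at least 2 frames",
                  "insufficient_frames")
  }
  check_number(frame_interval_s, "frame_interval_s", 0, strict = TRUE)
  maxval <- 2^bit_depth - 1
  rng <- range(frames)
  if (rng[1] < 0 || rng[2] > maxval) {
    stop_difcanal(
      sprintf("pixel values outside [0, %d] violate the declared %d-bit depth",
              maxval, bit_depth),
      "bit_depth_violation"
    )
  }
  storage.mode(frames) <- "integer"
  structure(
    list(
      frames = frames,
      frame_interval_s = frame_interval_s,
      dye_label = dye_label,
      bit_depth = as.integer(bit_depth),
      source = source,
      meta = meta
    ),
    class = "timelapse"
  )
}

#' @export
print.timelapse <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<timelapse> %s: %d frames of %dx%d px every %g s (%d-bit)\n",
    x$dye_label, d[3], d[1], d[2], x$frame_interval_s, x$bit_depth
  ))
  invisible(x)
}

#' @export
n_frames <- function(lapse) UseMethod("n_frames")

#' Number of frames in a lapse
#' @param lapse A [timelapse()] object.
#' @return Integer frame count.
#' @export
n_frames.timelapse <- function(lapse) dim(lapse$frames)[3]

sidecar_path <- function(path) {
  paste0(sub("\\.tiff?$", "", path, ignore.case = TRUE), ".meta.json")
}

#' Write a time-lapse stack to multi-page TIFF with a JSON sidecar
#'
#' Frames are stored as 16-bit grayscale pages (TIFF has no native 14-bit
#' type; the payload bit depth travels in the sidecar). The sidecar
#' `<name>.meta.json` holds `frame_interval_s`, `dye_label`, `bit_depth`,
#' `n_frames`, and any extra metadata attached to the lapse, so that
#' `read_stack(write_stack(x))` reproduces `x` bit-identically.
#'
#' @param lapse A [timelapse()] object.
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(lapse, path) {
  stopifnot(inherits(lapse, "timelapse"))
  d <- dim(lapse$frames)
  pages <- lapply(seq_len(d[3]), function(t) lapse$frames[, , t] / 65535)
  ok <- tryCatch(
    tiff::writeTIFF(pages, path, bits.per.sample = 16L),
    error = function(e) stop_difcanal(conditionMessage(e), "io")
  )
  meta <- c(
    list(
      frame_interval_s = lapse$frame_interval_s,
      dye_label = lapse$dye_label,
      bit_depth = lapse$bit_depth,
      n_frames = d[3]
    ),
    lapse$meta
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a time-lapse stack from multi-page TIFF
#'
#' Reads raw 16-bit counts (no rescaling) and merges the
#' `<name>.meta.json` sidecar when present. Validates the declared bit
#' depth, a uniform time base, and the minimum frame count.
#'
#' @param path Path to a multi-page TIFF written by [write_stack()] (or any
#'   16-bit grayscale stack).
#' @param expected_bit_depth Payload bit depth to validate against when the
#'   sidecar is absent; default 14.
#' @param frame_interval_s Frame interval fallback when the sidecar is
#'   absent; default 20 s.
#' @return A [timelapse()] object.
#' @export
read_stack <- function(path, expected_bit_depth = 14L,
                       frame_interval_s = 20) {
  if (!file.exists(path)) {
    stop_difcanal(sprintf("no such file: %s", path), "io")
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L) {
    stop_difcanal("stack has fewer than 2 frames", "insufficient_frames")
  }
  frames <- array(unlist(pages, use.names = FALSE),
                  dim = c(dim(pages[[1]]), length(pages)))
  meta <- list()
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  }
  interval <- as.numeric(meta$frame_interval_s %||% frame_interval_s)
  if (!is.null(meta$times)) {
    dt <- diff(as.numeric(meta$times))
    if (length(unique(round(dt, 9))) != 1L) {
      stop_difcanal("non-uniform frame timestamps in sidecar", "timing")
    }
    interval <- dt[1]
  }
  bd <- meta$bit_depth %||% expected_bit_depth
  extra <- meta[setdiff(names(meta),
                        c("frame_interval_s", "dye_label", "bit_depth",
                          "n_frames", "times"))]
  timelapse(frames,
    frame_interval_s = interval,
    dye_label = meta$dye_label %||% "FU",
    bit_depth = bd,
    source = path,
    meta = extra
  )
}
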