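#' Eye geometry for an en-face canalogram frame
#'
#' Describes where the eye sits in the image: the limbus circle (inside which
#' lies the anterior chamber, excluded from all quantification), the outer
#' boundary of the perilimbal annulus in which outflow channels fill with
#' dye, the eye's laterality, and the image orientation.
#'
#' @param width,height Image frame size in pixels (columns, rows).
#' @param center_x,center_y Eye center in pixel coordinates (column, row).
#'   Defaults to the frame center.
#' @param limbus_radius Limbus radius in pixels.
#' @param outer_radius Outer radius of the perilimbal annulus in pixels;
#'   defaults to `1.5 * limbus_radius`.
#' @param laterality `"OD"` (right eye) or `"OS"` (left eye). With an
#'   en-face view and superior up, nasal is image-left for OD and
#'   image-right for OS.
#' @param image_up_is_superior Logical; `TRUE` when decreasing row index
#'   points to the superior pole.
#'
#' @return An `eye_geometry` object.
#' @export
eye_geometry <- function(width, height,
                         center_x = (width + 1) / 2,
                         center_y = (height + 1) / 2,
                         limbus_radius,
                         outer_radius = 1.5 * limbus_radius,
                         laterality = c("OD", "OS"),
                         image_up_is_superior = TRUE) {
  laterality <- match.arg(laterality)
  check_number(width, "width", 1)
  check_number(height, "height", 1)
  check_number(limbus_radius, "limbus_radius", 0, strict = TRUE)
  check_number(outer_radius, "outer_radius", 0, strict = TRUE)
  if (outer_radius <= limbus_radius) {
    stop_difcanal("`outer_radius` must exceed `limbus_radius`",
                  "invalid_geometry")
  }
  geom <- structure(
    list(
      width = as.integer(width), height = as.integer(height),
      center_x = center_x, center_y = center_y,
      limbus_radius = limbus_radius, outer_radius = outer_radius,
      laterality = laterality,
      image_up_is_superior = isTRUE(image_up_is_superior)
    ),
    class = "eye_geometry"
  )
  validate_geometry_fits(geom)
  geom
}

validate_geometry_fits <- function(geom) {
  fits <- geom$center_x - geom$outer_radius >= 1 &&
    geom$center_x + geom$outer_radius <= geom$width &&
    geom$center_y - geom$outer_radius >= 1 &&
    geom$center_y + geom$outer_radius <= geom$height
  if (!fits) {
    stop_difcanal("perilimbal annulus does not fit inside the image frame",
                  "invalid_geometry")
  }
  invisible(geom)
}

#' @export
print.eye_geometry <- function(x, ...) {
  cat(sprintf(
    "<eye_geometry> %dx%d px, center (%.1f, %.1f), limbus r=%.1f, outer r=%.1f, %s%s\n",
    x$width, x$height, x$center_x, x$center_y, x$limbus_radius,
    x$outer_radius, x$laterality,
    if (x$image_up_is_superior) "" else " (image up = inferior)"
  ))
  invisible(x)
}

# Quadrant label of each image sector, honouring laterality and orientation.
# Screen sectors (counter-clockwise from image-right, with "up" = decreasing
# row): 1 upper-right, 2 upper-left, 3 lower-left, 4 lower-right.
sector_labels <- function(laterality, up_is_superior) {
  labs <- if (laterality == "OD") {
    c("ST", "SN", "IN", "IT") # nasal on image-left
  } else {
    c("SN", "ST", "IT", "IN") # nasal on image-right
  }
  if (!up_is_superior) {
    # vertical mirror: superior <-> inferior, nasal/temporal side unchanged
    labs <- paste0(chartr("SI", "IS", substr(labs, 1, 1)), substr(labs, 2, 2))
  }
  labs
}

# Integer matrix, height x width: 0 = outside annulus, 1..4 = index into
# QUADRANTS for the quadrant owning that pixel; -1 = anterior chamber disc.
quadrant_label_matrix <- function(geom) {
  validate_geometry_fits(geom)
  col <- matrix(seq_len(geom$width), geom$height, geom$width, byrow = TRUE)
  row <- matrix(seq_len(geom$height), geom$height, geom$width)
  dx <- col - geom$center_x
  dy <- geom$center_y - row # screen-up positive
  r <- sqrt(dx^2 + dy^2)
  theta <- (atan2(dy, dx) * 180 / pi) %% 360
  # half-open 90-degree sectors: a boundary angle belongs to the
  # counter-clockwise sector by construction of floor()
  sector <- floor(theta / 90) + 1L
  labs <- sector_labels(geom$laterality, geom$image_up_is_superior)
  lab_idx <- match(labs, QUADRANTS)[sector]
  out <- matrix(0L, geom$height, geom$width)
  in_annulus <- r >= geom$limbus_radius & r < geom$outer_radius
  out[in_annulus] <- lab_idx[in_annulus]
  out[r < geom$limbus_radius] <- -1L
  out
}

#' Perilimbal quadrant masks
#'
#' Splits the perilimbal annulus (`limbus_radius <= r < outer_radius`,
#' pixel-center distances from the eye center) into four 90-degree sectors on
#' the vertical and horizontal axes, labelled IN/SN/ST/IT according to
#' laterality. The anterior chamber (inside the limbus) is excluded so dye
#' pooling there never contaminates quantification. The four masks are
#' pairwise disjoint and their union is exactly the annulus; boundary pixels
#' tie-break to the counter-clockwise sector.
#'
#' @param geom An [eye_geometry()] object.
#' @return Named list of four logical `height x width` matrices, in
#'   [QUADRANTS] order.
#' @export
quadrant_masks <- function(geom) {
  lab <- quadrant_label_matrix(geom)
  masks <- lapply(seq_along(QUADRANTS), function(i) lab == i)
  names(masks) <- QUADRANTS
  masks
}

#' Anterior chamber disc mask
#'
#' Pixels strictly inside the limbus circle.
#'
#' @param geom An [eye_geometry()] object.
#' @return Logical `height x width` matrix.
#' @export
chamber_mask <- function(geom) {
  quadrant_label_matrix(geom) == -1L
}

#' Mean ROI intensity over time
#'
#' The per-frame arithmetic mean of the pixels under a mask -- the method's
#' basic read-out. Times are `(frame - 1) * frame_interval_s`.
#'
#' @param lapse A [timelapse()] object.
#' @param mask Logical matrix matching the frame shape.
#' @return An [intensity_trace()] tibble with columns `time` (s) and
#'   `value` (intensity units).
#' @export
mean_intensity_trace <- function(lapse, mask) {
  stopifnot(inherits(lapse, "timelapse"))
  d <- dim(lapse$frames)
  if (!is.logical(mask) || !identical(dim(mask), d[1:2])) {
    stop_difcanal("`mask` must be a logical matrix matching the frame shape",
                  "invalid_input")
  }
  npix <- sum(mask)
  if (npix == 0L) {
    stop_difcanal("empty ROI: mask selects no pixels", "empty_roi")
  }
  vals <- vapply(seq_len(d[3]), function(t) mean(lapse$frames[, , t][mask]),
                 numeric(1))
  intensity_trace((seq_len(d[3]) - 1) * lapse$frame_interval_s, vals)
}

#' Pooled perilimbal trace
#'
#' Mean intensity over the union of the four quadrant masks (the whole
#' perilimbal annulus); used to pick the half-maximum frame.
#'
#' @inheritParams mean_intensity_trace
#' @param geom An [eye_geometry()] object.
#' @param masks Optional precomputed [quadrant_masks()] result.
#' @return An [intensity_trace()].
#' @export
perilimbal_trace <- function(lapse, geom, masks = quadrant_masks(geom)) {
  union_mask <- Reduce(`|`, masks)
  mean_intensity_trace(lapse, union_mask)
}

#' Quadrant mean intensities at one frame
#'
#' @param lapse A [timelapse()] object.
#' @param geom An [eye_geometry()] object.
#' @param frame Frame index (1-based).
#' @param masks Optional precomputed [quadrant_masks()] result.
#' @return Tibble with columns `quadrant` and `intensity`.
#' @export
quadrant_intensities <- function(lapse, geom, frame,
                                 masks = quadrant_masks(geom)) {
  stopifnot(inherits(lapse, "timelapse"))
  d <- dim(lapse$frames)
  if (frame < 1 || frame > d[3]) {
    stop_difcanal("`frame` outside the lapse", "invalid_input")
  }
  img <- lapse$frames[, , frame]
  tibble(
    quadrant = factor(QUADRANTS, levels = QUADRANTS),
    intensity = unname(vapply(masks, function(m) mean(img[m]), numeric(1)))
  )
}

#' Export quadrant masks as a single-page TIFF for audit
#'
#' Writes a label image (0 background, then evenly spaced gray levels for
#' IN, SN, ST, IT, and the chamber disc at full white).
#'
#' @param geom An [eye_geometry()] object.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(geom, path) {
  lab <- quadrant_label_matrix(geom)
  img <- matrix(0, nrow(lab), ncol(lab))
  for (i in 1:4) img[lab == i] <- i / 5
  img[lab == -1L] <- 1
  tiff::writeTIFF(img, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read eye geometry from a YAML or JSON config
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file whose keys match the
#'   arguments of [eye_geometry()].
#' @return An [eye_geometry()] object.
#' @export
read_geometry <- function(path) {
  if (!file.exists(path)) {
    stop_difcanal(sprintf("no such file: %s", path), "io")
  }
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(eye_geometry, cfg)
}
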