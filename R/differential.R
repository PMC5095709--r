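#' Percent outflow change from a matched dye pair
#'
#' The core differential read-out: with the second dye rescaled by the
#' normalization coefficient, the per-quadrant percent change is
#' \deqn{\Delta_q = 100\,(c \cdot TR_q - FU_q) / FU_q.}
#'
#' @param fu_q Pre-surgical FU quadrant intensity (> 0). Vectorized.
#' @param tr_q Post-surgical TR quadrant intensity at the matched frame.
#' @param c Normalization coefficient (scalar or a `calibration_model`).
#' @return Percent change(s).
#' @export
percent_change <- function(fu_q, tr_q, c = 1) {
  if (inherits(c, "calibration_model")) c <- c$c
  if (any(!is.finite(fu_q)) || any(fu_q <= 0)) {
    stop_difcanal("FU intensities must be positive", "invalid_intensity")
  }
  100 * (c * tr_q - fu_q) / fu_q
}

#' Percent change between two flow rates
#'
#' @param before,after Flow rates in uL/min (`before` > 0).
#' @return Percent change `100 * (after/before - 1)`.
#' @export
flow_percent_change <- function(before, after) {
  if (any(!is.finite(before)) || any(before <= 0)) {
    stop_difcanal("`before` flow rates must be positive", "invalid_input")
  }
  100 * (after / before - 1)
}

#' Partition total aqueous inflow across quadrants
#'
#' Divides the eye's total aqueous humor flow rate (3 uL/min for porcine
#' eyes) among the four quadrants in proportion to their control
#' fluorescence: `flow_q = total * F_q / sum(F)`. The partition conserves
#' the total exactly, by construction.
#'
#' @param control_quadrant_fluorescence Four non-negative intensities in
#'   [QUADRANTS] order (names optional).
#' @param total_inflow Total inflow in uL/min; default 3.
#' @return Named numeric vector of baseline quadrant flows summing to
#'   `total_inflow`.
#' @export
flow_partition <- function(control_quadrant_fluorescence, total_inflow = 3) {
  f <- control_quadrant_fluorescence
  if (any(!is.finite(f)) || any(f < 0)) {
    stop_difcanal("quadrant fluorescence must be non-negative and finite",
                  "invalid_input")
  }
  if (sum(f) <= 0) {
    stop_difcanal("all-zero quadrant fluorescence cannot be partitioned",
                  "degenerate_input")
  }
  check_number(total_inflow, "total_inflow", 0, strict = TRUE)
  out <- total_inflow * f / sum(f)
  if (is.null(names(out)) && length(out) == 4) names(out) <- QUADRANTS
  out
}

#' Post-surgical flow from baseline flow and percent change
#'
#' @param baseline_q Baseline quadrant flow(s) in uL/min (>= 0).
#' @param percent_change_q Percent change(s); must be >= -100 (flow cannot
#'   go negative).
#' @return Post-surgical flow(s) in uL/min.
#' @export
flow_after <- function(baseline_q, percent_change_q) {
  if (any(!is.finite(baseline_q)) || any(baseline_q < 0)) {
    stop_difcanal("baseline flows must be non-negative", "invalid_input")
  }
  if (any(percent_change_q < -100)) {
    stop_difcanal("percent change below -100 would imply negative flow",
                  "invalid_change")
  }
  baseline_q * (1 + percent_change_q / 100)
}

#' Run the differential canalogram on one eye
#'
#' The full quantification pipeline for a pre-surgical fluorescein lapse and
#' a post-surgical Texas red lapse of the same eye:
#' \enumerate{
#'   \item pick the half-maximum frame of the pooled perilimbal FU trace;
#'   \item measure the four quadrant means in both lapses at that frame;
#'   \item rescale TR by the normalization coefficient `c`;
#'   \item compute per-quadrant percent change \eqn{\Delta_q};
#'   \item partition `total_inflow` across quadrants by the control
#'     fluorescence (by default the same eye's FU quadrant values;
#'     supply `control_fluorescence` to use an external control group);
#'   \item convert \eqn{\Delta_q} into post-surgical flows.
#' }
#'
#' @param fu_lapse,tr_lapse [timelapse()]s of one eye (same shape and
#'   frame interval).
#' @param geom An [eye_geometry()].
#' @param calib A `calibration_model` (or scalar coefficient).
#' @param total_inflow Total aqueous inflow in uL/min; default 3.
#' @param control_fluorescence Optional four control quadrant intensities
#'   for the flow partition; default: the eye's own FU values.
#' @param masks Optional precomputed [quadrant_masks()].
#' @return A `canalogram_result`: a tibble with one row per quadrant
#'   (`quadrant`, `fu`, `tr_corrected`, `percent_change`, `flow_before`,
#'   `flow_after`) carrying `half_max_frame`, `c_used` and `total_inflow`
#'   as attributes.
#' @export
run_differential <- function(fu_lapse, tr_lapse, geom, calib,
                             total_inflow = 3, control_fluorescence = NULL,
                             masks = quadrant_masks(geom)) {
  if (inherits(calib, "calibration_model")) calib <- calib$c
  check_number(calib, "calib", 0, strict = TRUE)
  m <- matched_quadrant_intensities(fu_lapse, tr_lapse, geom, masks)
  delta <- percent_change(m$fu, m$tr, calib)
  ctrl <- control_fluorescence %||% m$fu
  before <- flow_partition(ctrl, total_inflow)
  after <- flow_after(before, delta)
  res <- tibble(
    quadrant = m$quadrant,
    fu = m$fu,
    tr_corrected = calib * m$tr,
    percent_change = delta,
    flow_before = unname(before),
    flow_after = unname(after)
  )
  structure(res,
    class = c("canalogram_result", class(tibble())),
    half_max_frame = m$frame[1],
    c_used = calib,
    total_inflow = total_inflow,
    geometry = geom
  )
}

#' @export
print.canalogram_result <- function(x, ...) {
  cat(sprintf(
    "<canalogram_result> frame %d, c = %.3f, total inflow %.1f uL/min\n",
    attr(x, "half_max_frame"), attr(x, "c_used"), attr(x, "total_inflow")
  ))
  disp <- dplyr::mutate(
    as_tibble(x),
    percent_change = round(.data$percent_change),
    flow_before = round(.data$flow_before, 2),
    flow_after = round(.data$flow_after, 2)
  )
  print(disp, ...)
  invisible(x)
}

#' Write a canalogram result as JSON plus tidy CSV
#'
#' @param result A `canalogram_result`.
#' @param path Output path stem or `.json` path; the CSV lands next to it.
#' @return The JSON path, invisibly.
#' @export
write_result <- function(result, path) {
  stopifnot(inherits(result, "canalogram_result"))
  stem <- sub("\\.json$", "", path)
  payload <- list(
    half_max_frame = attr(result, "half_max_frame"),
    c_used = attr(result, "c_used"),
    total_inflow = attr(result, "total_inflow"),
    quadrants = as.data.frame(result)
  )
  jsonlite::write_json(payload, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  utils::write.csv(as.data.frame(result), paste0(stem, ".csv"),
                   row.names = FALSE)
  invisible(paste0(stem, ".json"))
}
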