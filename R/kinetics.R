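#' Intensity trace
#'
#' A per-frame mean ROI intensity over time, as a tidy tibble with columns
#' `time` (seconds, strictly increasing) and `value` (intensity units).
#'
#' @param times Times in seconds, strictly increasing.
#' @param values Intensities, same length as `times`.
#' @return An `intensity_trace` tibble.
#' @export
intensity_trace <- function(times, values) {
  if (length(times) != length(values)) {
    stop_difcanal("`times` and `values` must have equal length",
                  "invalid_input")
  }
  if (length(times) && any(diff(times) <= 0)) {
    stop_difcanal("`times` must be strictly increasing", "invalid_input")
  }
  structure(tibble(time = as.numeric(times), value = as.numeric(values)),
            class = c("intensity_trace", class(tibble())))
}

trace_check <- function(trace) {
  if (!is.data.frame(trace) || !all(c("time", "value") %in% names(trace))) {
    stop_difcanal("expected an intensity trace with `time` and `value` columns",
                  "invalid_input")
  }
  trace
}

#' Initial dye filling time
#'
#' The earliest time at which a trace rises detectably above its own
#' baseline: `value > baseline_mean + k * baseline_sd`, with the baseline
#' estimated from the first `baseline_frames` frames. This operationalizes
#' "the time at which dye is first observed entering the proximal outflow
#' tract"; `k` trades sensitivity against false alarms.
#'
#' @param trace An [intensity_trace()].
#' @param k Threshold in baseline SDs; default 3.
#' @param baseline_frames Frames used for the baseline estimate; default 3.
#' @return Time in seconds, or `NA_real_` if the threshold is never crossed.
#' @export
initial_filling_time <- function(trace, k = 3, baseline_frames = 3) {
  trace_check(trace)
  if (nrow(trace) < baseline_frames + 1) {
    stop_difcanal(
      sprintf("trace shorter than the %d-frame baseline window plus one frame",
              baseline_frames),
      "insufficient_data"
    )
  }
  base <- trace$value[seq_len(baseline_frames)]
  thr <- mean(base) + k * sd(base)
  hit <- which(trace$value > thr)
  if (!length(hit)) NA_real_ else trace$time[hit[1]]
}

#' Half-maximum frame
#'
#' The frame whose intensity best matches half the trace maximum -- the
#' common read-out time point at which both dyes of a pair are measured.
#' Ties break toward the earlier frame.
#'
#' @param trace An [intensity_trace()].
#' @return 1-based frame index.
#' @export
half_max_frame <- function(trace) {
  trace_check(trace)
  v <- trace$value
  if (diff(range(v)) == 0) {
    stop_difcanal("constant trace has no half-maximum frame",
                  "degenerate_trace")
  }
  which.min(abs(v - 0.5 * max(v)))
}

#' Least-squares slope of a trace
#'
#' Fitted over a frame window; by default from the first frame above
#' baseline (per [initial_filling_time()]) through the half-maximum frame,
#' i.e. the early quasi-linear rise.
#'
#' @param trace An [intensity_trace()].
#' @param window Integer frame indices to fit over; `NULL` for the default
#'   onset-to-half-max window.
#' @return Slope in intensity units per second.
#' @export
fit_slope <- function(trace, window = NULL) {
  trace_check(trace)
  if (is.null(window)) {
    t0 <- initial_filling_time(trace)
    if (is.na(t0)) {
      stop_difcanal("no onset detected; supply `window` explicitly",
                    "insufficient_data")
    }
    window <- seq(match(t0, trace$time), half_max_frame(trace))
  }
  if (length(unique(window)) < 2 ||
      any(window < 1) || any(window > nrow(trace))) {
    stop_difcanal("slope window must contain at least 2 frames inside the trace",
                  "insufficient_data")
  }
  x <- trace$time[window]
  y <- trace$value[window]
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Screen a concentration series for dynamic quenching
#'
#' Given intensities measured at strictly increasing concentrations (e.g. a
#' logarithmic dilution series), returns the smallest concentration at which
#' intensity drops below the previous point -- the onset of the self-quench
#' regime -- or `NA` if the series never decreases.
#'
#' @param concentrations Strictly increasing concentrations (mg/mL),
#'   at least 3 points.
#' @param intensities Measured intensities, same length.
#' @return Quench onset concentration, or `NA_real_`.
#' @seealso [is_quench_safe()]
#' @export
quench_scan <- function(concentrations, intensities) {
  if (length(concentrations) < 3 ||
      length(concentrations) != length(intensities)) {
    stop_difcanal("need >= 3 matched concentration/intensity points",
                  "invalid_input")
  }
  if (any(diff(concentrations) <= 0)) {
    stop_difcanal("`concentrations` must be strictly increasing",
                  "invalid_input")
  }
  drop <- which(diff(intensities) < 0)
  if (!length(drop)) NA_real_ else concentrations[drop[1] + 1L]
}

#' Is a working concentration below the quench onset?
#'
#' @param working_concentration Concentration to check (mg/mL).
#' @param onset Quench onset from [quench_scan()] (`NA` = no quenching
#'   observed anywhere in the tested range).
#' @return `TRUE` if the working point is safe.
#' @export
is_quench_safe <- function(working_concentration, onset) {
  is.na(onset) || working_concentration < onset
}

#' Quadrant intensities of a dye pair at the FU half-maximum frame
#'
#' Selects the half-maximum frame of the fluorescein lapse from its pooled
#' perilimbal trace, then measures all four quadrants in both lapses at that
#' same frame number (the second dye is read at the first dye's matched
#' time point).
#'
#' @param fu_lapse,tr_lapse [timelapse()]s of the same eye, same shape and
#'   frame interval.
#' @param geom An [eye_geometry()].
#' @param masks Optional precomputed [quadrant_masks()].
#' @return Tibble with columns `quadrant`, `frame`, `fu`, `tr`.
#' @export
matched_quadrant_intensities <- function(fu_lapse, tr_lapse, geom,
                                         masks = quadrant_masks(geom)) {
  check_compatible_lapses(fu_lapse, tr_lapse)
  h <- half_max_frame(perilimbal_trace(fu_lapse, geom, masks))
  fu_q <- quadrant_intensities(fu_lapse, geom, h, masks)
  tr_q <- quadrant_intensities(tr_lapse, geom, h, masks)
  tibble(
    quadrant = fu_q$quadrant, frame = h,
    fu = fu_q$intensity, tr = tr_q$intensity
  )
}

check_compatible_lapses <- function(fu_lapse, tr_lapse) {
  stopifnot(inherits(fu_lapse, "timelapse"), inherits(tr_lapse, "timelapse"))
  if (!identical(dim(fu_lapse$frames), dim(tr_lapse$frames)) ||
      fu_lapse$frame_interval_s != tr_lapse$frame_interval_s) {
    stop_difcanal("the two lapses must share frame shape and interval",
                  "incompatible_lapses")
  }
  invisible(TRUE)
}

#' Estimate the TR-to-FU normalization coefficient
#'
#' The coefficient `c` rescales the second dye's (TR) intensities onto the
#' first dye's (FU) scale, computed from control eyes in which no
#' intervention separates the two lapses. Per eye, the ratio is the mean
#' over quadrants of `fu/tr` at the FU half-maximum matched frame;
#' `c` is the mean of the per-eye ratios (`method = "per_eye"`, default) or
#' the mean over all quadrant measurements pooled (`method = "pooled"`).
#'
#' @param control_pairs Data frame with columns `eye`, `quadrant`, `fu`,
#'   `tr` -- e.g. from [simulate_control_pairs()] or repeated
#'   [matched_quadrant_intensities()] calls.
#' @param method `"per_eye"` or `"pooled"`.
#' @return A `calibration_model` with fields `c`, `per_eye_ratios`,
#'   `n_eyes`, `method`.
#' @export
estimate_normalization <- function(control_pairs,
                                   method = c("per_eye", "pooled")) {
  method <- match.arg(method)
  if (!is.data.frame(control_pairs) ||
      !all(c("eye", "quadrant", "fu", "tr") %in% names(control_pairs)) ||
      nrow(control_pairs) == 0) {
    stop_difcanal(
      "`control_pairs` must have columns eye, quadrant, fu, tr and >= 1 row",
      "invalid_input"
    )
  }
  if (any(control_pairs$tr <= 0) || any(control_pairs$fu <= 0)) {
    stop_difcanal("all FU and TR intensities must be positive",
                  "invalid_intensity")
  }
  per_eye <- control_pairs |>
    dplyr::group_by(.data$eye) |>
    dplyr::summarise(ratio = mean(.data$fu / .data$tr), .groups = "drop")
  cc <- switch(method,
    per_eye = mean(per_eye$ratio),
    pooled = mean(control_pairs$fu / control_pairs$tr)
  )
  structure(
    list(c = cc, per_eye_ratios = setNames(per_eye$ratio, per_eye$eye),
         n_eyes = nrow(per_eye), method = method),
    class = "calibration_model"
  )
}

#' Construct a calibration model directly
#'
#' For when `c` comes from an external calibration run rather than from
#' [estimate_normalization()].
#'
#' @param c Positive normalization coefficient.
#' @return A `calibration_model`.
#' @export
calibration_model <- function(c) {
  check_number(c, "c", 0, strict = TRUE)
  structure(list(c = c, per_eye_ratios = c, n_eyes = 1L, method = "fixed"),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> c = %.4f (%s, n_eyes = %d)\n",
              x$c, x$method, x$n_eyes))
  invisible(x)
}

#' Write / read a calibration model as JSON
#'
#' @param calib A `calibration_model`.
#' @param path JSON path.
#' @return `path` (write) or a `calibration_model` (read).
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "calibration_model"))
  jsonlite::write_json(unclass(calib), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(c = x$c, per_eye_ratios = unlist(x$per_eye_ratios),
         n_eyes = x$n_eyes, method = x$method %||% "per_eye"),
    class = "calibration_model"
  )
}
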