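#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a calibration model
#'
#' One row per control eye with its FU/TR ratio.
#'
#' @param x A `calibration_model`.
#' @param ... Unused.
#' @return Tibble with columns `eye` and `ratio`.
#' @method tidy calibration_model
#' @export
tidy.calibration_model <- function(x, ...) {
  tibble(eye = names(x$per_eye_ratios) %||% as.character(seq_along(x$per_eye_ratios)),
         ratio = unname(x$per_eye_ratios))
}

#' Glance at a calibration model
#'
#' @param x A `calibration_model`.
#' @param ... Unused.
#' @return One-row tibble: `c`, `n_eyes`, `method`.
#' @method glance calibration_model
#' @export
glance.calibration_model <- function(x, ...) {
  tibble(c = x$c, n_eyes = x$n_eyes, method = x$method)
}

#' Tidy a differential canalogram result
#'
#' @param x A `canalogram_result`.
#' @param ... Unused.
#' @return A plain tibble, one row per quadrant.
#' @method tidy canalogram_result
#' @export
tidy.canalogram_result <- function(x, ...) {
  as_tibble(x)
}

#' Glance at a differential canalogram result
#'
#' @param x A `canalogram_result`.
#' @param ... Unused.
#' @return One-row tibble: `half_max_frame`, `c_used`, `total_inflow`,
#'   `mean_percent_change`, `total_flow_after`.
#' @method glance canalogram_result
#' @export
glance.canalogram_result <- function(x, ...) {
  tibble(
    half_max_frame = attr(x, "half_max_frame"),
    c_used = attr(x, "c_used"),
    total_inflow = attr(x, "total_inflow"),
    mean_percent_change = mean(x$percent_change),
    total_flow_after = sum(x$flow_after)
  )
}
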