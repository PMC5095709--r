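#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an intensity trace
#'
#' @param object An [intensity_trace()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot intensity_trace
#' @export
autoplot.intensity_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "mean ROI intensity (camera units)") +
    ggplot2::theme_minimal()
}

#' Plot per-quadrant percent outflow change
#'
#' @param object A `canalogram_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot canalogram_result
#' @export
autoplot.canalogram_result <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$quadrant, y = .data$percent_change)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "outflow change (%)") +
    ggplot2::theme_minimal()
}

#' Plot a group summary with SEM error bars
#'
#' @param object A `canalogram_group_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot canalogram_group_summary
#' @export
autoplot.canalogram_group_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$quadrant, y = .data$mean_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_pct - .data$sem_pct,
                   ymax = .data$mean_pct + .data$sem_pct),
      width = 0.2
    ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "mean outflow change (%, +/- SEM)") +
    ggplot2::theme_minimal()
}

#' Show the quadrant layout of a geometry
#'
#' Raster plot of the four perilimbal quadrant masks and the excluded
#' anterior chamber; useful to audit laterality conventions.
#'
#' @param geom An [eye_geometry()].
#' @return A ggplot.
#' @export
plot_quadrant_masks <- function(geom) {
  lab <- quadrant_label_matrix(geom)
  df <- tibble(
    row = as.vector(row(lab)),
    col = as.vector(col(lab)),
    region = factor(
      dplyr::case_when(
        as.vector(lab) == -1L ~ "chamber",
        as.vector(lab) == 0L ~ "outside",
        TRUE ~ QUADRANTS[pmax(as.vector(lab), 1L)]
      ),
      levels = c(QUADRANTS, "chamber", "outside")
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$region)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
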