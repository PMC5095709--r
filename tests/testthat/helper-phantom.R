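# Small-frame configurations so phantom-based tests run quickly; the
# kinetics (time base, delays, slopes) are identical to the defaults --
# only the pixel grid shrinks.

small_acq <- function(...) {
  acquisition_config(width = 101L, height = 101L, ...)
}

small_geom <- function(acq = small_acq(), laterality = "OD", ...) {
  eye_geometry(
    width = acq$width, height = acq$height,
    center_x = 51, center_y = 51,
    limbus_radius = 20, outer_radius = 30,
    laterality = laterality, ...
  )
}

# a noiseless, jitter-free control pair rendered directly (no per-eye
# biological variability), for exactness tests
noiseless_pair <- function(flow = uniform_flow_map(),
                           effect = surgery_effect("none"),
                           background_level = 200, chamber = TRUE) {
  acq <- small_acq(noise_sd = 0, background_level = background_level)
  geom <- small_geom(acq)
  fu <- render_timelapse(geom, flow, fu_dye(), acq, chamber = chamber)
  tr <- render_timelapse(geom, apply_surgery(flow, effect), tr_dye(), acq,
                         chamber = chamber)
  list(fu = fu, tr = tr, geom = geom, acq = acq)
}

# build a canalogram_result directly from known quadrant deltas and flows
# (for group-summary arithmetic tests)
make_result <- function(deltas, flows_before = c(0.82, 0.85, 0.62, 0.71),
                        geom = small_geom()) {
  structure(
    tibble::tibble(
      quadrant = factor(QUADRANTS, levels = QUADRANTS),
      fu = rep(1000, 4),
      tr_corrected = 1000 * (1 + deltas / 100),
      percent_change = deltas,
      flow_before = flows_before,
      flow_after = flows_before * (1 + deltas / 100)
    ),
    class = c("canalogram_result", class(tibble::tibble())),
    half_max_frame = 23L, c_used = 1.56, total_inflow = sum(flows_before),
    geometry = geom
  )
}
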