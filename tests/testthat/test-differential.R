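test_that("percent change arithmetic matches its definition", {
  expect_equal(percent_change(fu_q = 156, tr_q = 100, c = 1.56), 0)
  expect_equal(percent_change(fu_q = 100, tr_q = 100, c = 1.56), 56)
  expect_equal(percent_change(fu_q = 200, tr_q = 150, c = 2), 50)
  expect_error(percent_change(0, 10, 1),
               class = "difcanal_error_invalid_intensity")
})

test_that("flow partition conserves the total inflow exactly", {
  expect_equal(flow_partition(c(5, 5, 5, 5)),
               c(IN = 0.75, SN = 0.75, ST = 0.75, IT = 0.75))

  # the control relative fluorescence reproduces the printed baselines
  baselines <- flow_partition(c(0.2733, 0.2833, 0.2067, 0.2367))
  expect_equal(round(unname(baselines), 2), c(0.82, 0.85, 0.62, 0.71))

  set.seed(8)
  for (i in 1:50) {
    f <- runif(4, 0, 1000)
    expect_equal(sum(flow_partition(f)), 3)
    expect_equal(sum(flow_partition(f, total_inflow = 2.5)), 2.5)
  }
  expect_error(flow_partition(c(0, 0, 0, 0)),
               class = "difcanal_error_degenerate_input")
  expect_error(flow_partition(c(-1, 2, 3, 4)),
               class = "difcanal_error_invalid_input")
})

test_that("post-surgical flow recomputes the printed rate pairs", {
  expect_equal(flow_after(0.85, 0), 0.85)
  expect_equal(round(flow_after(0.85, 14.1), 2), 0.97)
  expect_equal(round(flow_after(0.87, 74.7), 2), 1.52)
  expect_error(flow_after(0.85, -101),
               class = "difcanal_error_invalid_change")
})

test_that("an eye compared against itself shows zero change", {
  acq <- small_acq(seed = 14)
  geom <- small_geom(acq)
  lapse <- render_timelapse(geom, control_flow_map(), fu_dye(), acq)
  res <- run_differential(lapse, lapse, geom, calib = 1)
  expect_equal(res$percent_change, rep(0, 4))
  expect_equal(res$flow_after, res$flow_before)
  expect_equal(sum(res$flow_before), 3)
})

test_that("noiseless phantom recovery is exact to rounding", {
  # uniform baseline, zero background, no noise, no per-eye jitter: the
  # self-calibrated pipeline must return exactly 100 * (multiplier - 1)
  ctrl <- noiseless_pair(background_level = 0)
  cal <- estimate_normalization(
    dplyr::mutate(matched_quadrant_intensities(ctrl$fu, ctrl$tr, ctrl$geom),
                  eye = 1)
  )
  effect <- surgery_effect("AIT")
  surg <- noiseless_pair(effect = effect, background_level = 0)
  res <- run_differential(surg$fu, surg$tr, surg$geom, cal)
  truth <- 100 * (unname(effect$quadrant_multipliers) - 1)
  expect_equal(res$percent_change, truth, tolerance = 0.005)
  # consistency invariant: delta from intensities == delta from flows
  expect_equal(res$percent_change,
               flow_percent_change(res$flow_before, res$flow_after))
})

test_that("a focal stent moves only its own quadrant above the noise floor", {
  acq <- small_acq(seed = 31)
  geom <- small_geom(acq)
  ctrl_fu <- render_timelapse(geom, control_flow_map(), fu_dye(), acq)
  ctrl_tr <- render_timelapse(geom, control_flow_map(), tr_dye(),
                              small_acq(seed = 32))
  cal <- estimate_normalization(
    dplyr::mutate(matched_quadrant_intensities(ctrl_fu, ctrl_tr, geom),
                  eye = 1)
  )
  effect <- surgery_effect("TMB", site_angle = 45, tmb_multiplier = 1.5)
  post <- apply_surgery(control_flow_map(), effect)
  tr <- render_timelapse(geom, post, tr_dye(), small_acq(seed = 33))
  res <- run_differential(ctrl_fu, tr, geom, cal)
  delta <- setNames(res$percent_change, as.character(res$quadrant))
  expect_gt(delta[["SN"]], 25)
  expect_true(all(abs(delta[c("IN", "ST", "IT")]) < 10))
})

test_that("recovered change is monotone in the ground-truth multiplier", {
  ctrl <- noiseless_pair(background_level = 0)
  cal <- estimate_normalization(
    dplyr::mutate(matched_quadrant_intensities(ctrl$fu, ctrl$tr, ctrl$geom),
                  eye = 1)
  )
  deltas <- vapply(c(1.0, 1.2, 1.5, 2.0), function(m) {
    eff <- surgery_effect("TMB", site_angle = 45, tmb_multiplier = m)
    p <- noiseless_pair(effect = eff, background_level = 0)
    res <- run_differential(p$fu, p$tr, p$geom, cal)
    res$percent_change[res$quadrant == "SN"]
  }, numeric(1))
  expect_true(all(diff(deltas) > 0))
})

test_that("incompatible lapses and degenerate inputs are rejected", {
  acq <- small_acq(seed = 2)
  geom <- small_geom(acq)
  a <- render_timelapse(geom, control_flow_map(), fu_dye(), acq)
  short <- timelapse(a$frames[, , 1:10], a$frame_interval_s)
  expect_error(run_differential(a, short, geom, 1.56),
               class = "difcanal_error_incompatible_lapses")
  slow <- timelapse(a$frames, frame_interval_s = 60)
  expect_error(run_differential(a, slow, geom, 1.56),
               class = "difcanal_error_incompatible_lapses")
})

test_that("results serialize to JSON + CSV and expose tidy/glance", {
  acq <- small_acq(seed = 17)
  geom <- small_geom(acq)
  eye <- simulate_eye(17, effect = surgery_effect("AIT"), geom = geom,
                      acq = acq)
  res <- run_differential(eye$fu, eye$tr, geom, calibration_model(1.56))
  dir <- withr::local_tempdir()
  write_result(res, file.path(dir, "res"))
  expect_true(file.exists(file.path(dir, "res.json")))
  back <- jsonlite::read_json(file.path(dir, "res.json"),
                              simplifyVector = TRUE)
  expect_equal(back$quadrants$percent_change, res$percent_change)
  csv <- utils::read.csv(file.path(dir, "res.csv"))
  expect_equal(nrow(csv), 4)
  expect_equal(glance(res)$c_used, 1.56)
  expect_s3_class(tidy(res), "tbl_df")
})
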