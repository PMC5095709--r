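test_that("initial filling time is the first rise above baseline", {
  tt <- (0:45) * 20
  flat <- intensity_trace(tt, rep(100, 46))
  expect_true(is.na(initial_filling_time(flat)))

  # noiseless ramp beginning between frames 10 and 11: first frame above
  # baseline is t = 200 s
  ramp <- intensity_trace(tt, 100 + 2 * pmax(0, tt - 190))
  expect_equal(initial_filling_time(ramp), 200)

  expect_error(initial_filling_time(intensity_trace(0:2, c(1, 1, 2))),
               class = "difcanal_error_insufficient_data")
})

test_that("half-maximum frame matches the definition, with earlier-frame ties", {
  expect_equal(half_max_frame(intensity_trace(0:3, c(0, 10, 40, 100))), 3)
  expect_equal(half_max_frame(intensity_trace(0:3, c(0, 50, 100, 50))), 2)
  # linear ramp from 0 over 46 frames: half-max sits between frames; the
  # tie breaks to the earlier one (value 22 s of 45 s)
  expect_equal(half_max_frame(intensity_trace((0:45) * 20, (0:45) * 7)), 23)
  expect_error(half_max_frame(intensity_trace(0:3, rep(2, 4))),
               class = "difcanal_error_degenerate_trace")
})

test_that("half-maximum frame equals the exhaustive-scan oracle on random traces", {
  oracle <- function(v) {
    best <- 1
    for (i in seq_along(v)) {
      if (abs(v[i] - 0.5 * max(v)) < abs(v[best] - 0.5 * max(v))) best <- i
    }
    best
  }
  set.seed(99)
  for (i in 1:200) {
    n <- sample(3:60, 1)
    v <- round(cumsum(rnorm(n, 1)), 2)
    if (diff(range(v)) == 0) next
    expect_equal(half_max_frame(intensity_trace(seq_len(n), v)),
                 oracle(v))
  }
})

test_that("fitted slopes are exact on lines and antisymmetric under reversal", {
  tt <- (0:20) * 20
  line <- intensity_trace(tt, 3 + 0.37 * tt)
  expect_equal(fit_slope(line, window = 1:21), 0.37)
  set.seed(4)
  v <- cumsum(abs(rnorm(21)))
  fwd <- fit_slope(intensity_trace(tt, v), window = 1:21)
  rev <- fit_slope(intensity_trace(tt, base::rev(v)), window = 1:21)
  expect_equal(rev, -fwd)
  expect_error(fit_slope(line, window = 5L),
               class = "difcanal_error_insufficient_data")
})

test_that("Texas red rises more steeply than fluorescein early on", {
  acq <- small_acq(noise_sd = 0)
  geom <- small_geom(acq)
  masks <- quadrant_masks(geom)
  fu <- render_timelapse(geom, control_flow_map(), fu_dye(), acq)
  tr <- render_timelapse(geom, control_flow_map(), tr_dye(), acq)
  for (q in QUADRANTS) {
    win <- 7:11 # post-onset, pre-plateau for both dyes
    expect_gt(fit_slope(mean_intensity_trace(tr, masks[[q]]), win),
              fit_slope(mean_intensity_trace(fu, masks[[q]]), win))
  }
  # and TR saturates at a lower peak than FU
  pool_fu <- perilimbal_trace(fu, geom, masks)
  pool_tr <- perilimbal_trace(tr, geom, masks)
  expect_lt(max(pool_tr$value), max(pool_fu$value))
})

test_that("quench_scan finds the self-quench onset and clears safe series", {
  expect_true(is.na(quench_scan(1:5, c(1, 2, 3, 4, 5))))

  # phantom response sampled at {0.1, 0.5, 1, 2, 5} x Cq: first decrease at 2 Cq
  cq <- fu_dye()$quench_scale
  conc <- c(0.1, 0.5, 1, 2, 5) * cq
  onset <- quench_scan(conc, intensity_from_concentration(fu_dye(), conc))
  expect_equal(onset, 2 * cq)
  expect_false(is_quench_safe(2.5 * cq, onset))
  expect_true(is_quench_safe(0.5 * cq, onset))

  # both default working concentrations are safe under the default physics
  for (dye in list(fu_dye(), tr_dye())) {
    series <- c(0.01, 0.1, 1, 10) * dye$working_concentration
    onset <- quench_scan(series, intensity_from_concentration(dye, series))
    expect_true(is_quench_safe(dye$working_concentration, onset))
  }

  expect_error(quench_scan(c(1, 3, 2), c(1, 2, 3)),
               class = "difcanal_error_invalid_input")
  expect_error(quench_scan(1:2, 1:2),
               class = "difcanal_error_invalid_input")
})

test_that("quench onset is invariant to uniform intensity rescaling", {
  cq <- 1.4
  conc <- c(0.1, 0.3, 1, 2, 4, 8) * cq
  resp <- conc * exp(-conc / cq)
  expect_equal(quench_scan(conc, resp), quench_scan(conc, 417.3 * resp))
})

test_that("normalization estimation follows the per-eye-then-average definition", {
  one_eye <- tibble::tibble(eye = 1, quadrant = QUADRANTS,
                            fu = c(150, 160, 150, 160),
                            tr = c(100, 100, 100, 100))
  expect_equal(estimate_normalization(one_eye)$c, 1.55)

  ident <- dplyr::mutate(one_eye, tr = fu)
  expect_equal(estimate_normalization(ident)$c, 1)

  # scale equivariance: multiplying all TR by s divides c by s
  cal <- estimate_normalization(one_eye)
  scaled <- estimate_normalization(dplyr::mutate(one_eye, tr = tr * 2))
  expect_equal(scaled$c, cal$c / 2)

  # per-eye vs pooled differ when eyes have different quadrant counts... or
  # different within-eye spread; both are averages of ratios
  two_eyes <- dplyr::bind_rows(
    one_eye,
    tibble::tibble(eye = 2, quadrant = QUADRANTS, fu = 200, tr = 100)
  )
  expect_equal(estimate_normalization(two_eyes)$c, mean(c(1.55, 2)))
  expect_equal(estimate_normalization(two_eyes, method = "pooled")$c,
               mean(c(1.5, 1.6, 1.5, 1.6, 2, 2, 2, 2)))
  expect_equal(estimate_normalization(two_eyes)$n_eyes, 2L)

  expect_error(estimate_normalization(dplyr::mutate(one_eye, tr = 0)),
               class = "difcanal_error_invalid_intensity")
})

test_that("calibration models round-trip through JSON", {
  cal <- estimate_normalization(
    tibble::tibble(eye = rep(1:2, each = 4), quadrant = rep(QUADRANTS, 2),
                   fu = 156, tr = 100)
  )
  path <- file.path(withr::local_tempdir(), "calib.json")
  write_calibration(cal, path)
  back <- read_calibration(path)
  expect_equal(back$c, cal$c)
  expect_equal(back$n_eyes, cal$n_eyes)
  expect_equal(tidy(back)$ratio, unname(cal$per_eye_ratios))
  expect_equal(glance(cal)$c, 1.56)
})
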