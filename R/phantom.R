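#' Per-quadrant relative outflow map
#'
#' Relative conventional-outflow fractions for the four perilimbal
#' quadrants. A baseline (pre-surgical) map sums to 1; a post-surgical map
#' produced by [apply_surgery()] represents enhanced flow and need not.
#'
#' @param IN,SN,ST,IT Non-negative relative flow fractions.
#' @param focal_site_angle Optional anatomical angle (degrees) of a focal
#'   feature; 0 = nasal, 90 = superior, 180 = temporal, 270 = inferior.
#' @return A `flow_map` object (named numeric vector).
#' @export
flow_map <- function(IN, SN, ST, IT, focal_site_angle = NULL) {
  f <- c(IN = IN, SN = SN, ST = ST, IT = IT)
  if (!is.numeric(f) || any(!is.finite(f)) || any(f < 0)) {
    stop_difcanal("flow fractions must be finite and >= 0", "invalid_input")
  }
  structure(f, focal_site_angle = focal_site_angle, class = "flow_map")
}

#' Default control flow map
#'
#' Baseline per-quadrant fractions (0.2733, 0.2833, 0.2067, 0.2367) for
#' (IN, SN, ST, IT): the relative quadrant fluorescence measured in control
#' porcine eyes, i.e. the per-quadrant shares of the 3 uL/min aqueous
#' inflow (0.82, 0.85, 0.62, 0.71 uL/min).
#'
#' @return A [flow_map()].
#' @export
control_flow_map <- function() {
  flow_map(IN = 0.2733, SN = 0.2833, ST = 0.2067, IT = 0.2367)
}

#' Uniform flow map
#' @return A [flow_map()] with 0.25 in every quadrant.
#' @export
uniform_flow_map <- function() flow_map(0.25, 0.25, 0.25, 0.25)

#' Anatomical quadrant containing an angle
#'
#' Angles are anatomical: 0 = nasal, 90 = superior, 180 = temporal,
#' 270 = inferior (counter-clockwise), so e.g. 45 degrees lies in SN.
#'
#' @param angle Angle in degrees.
#' @return One of [QUADRANTS].
#' @export
quadrant_of_angle <- function(angle) {
  a <- angle %% 360
  c("SN", "ST", "IT", "IN")[floor(a / 90) + 1L]
}

#' Surgical intervention effect on quadrant outflow
#'
#' Encodes how an intervention rescales quadrant outflow in the phantom.
#' `"TMB"` (trabecular micro-bypass stent) is focal: by default only the
#' quadrant containing `site_angle` is boosted. `"AIT"` (ab interno
#' trabeculectomy of the nasal angle) is circumferential-nasal: the default
#' multipliers (2.00, 1.75, 1.19, 1.40) boost IN and SN strongly and
#' ST/IT mildly. `"none"` leaves every quadrant at multiplier 1.
#'
#' @param kind One of `"none"`, `"TMB"`, `"AIT"`.
#' @param site_angle Anatomical angle (degrees) of the surgical site; used
#'   by the focal TMB default. Default 225 (mid-inferotemporal).
#' @param multipliers Optional named numeric vector over [QUADRANTS]
#'   overriding the defaults; must be non-negative.
#' @param tmb_multiplier Boost applied to the stented quadrant when
#'   `kind = "TMB"` and `multipliers` is not given; default 1.24.
#' @return A `surgery_effect` object.
#' @export
surgery_effect <- function(kind = c("none", "TMB", "AIT"),
                           site_angle = 225,
                           multipliers = NULL,
                           tmb_multiplier = 1.24) {
  kind <- match.arg(kind)
  if (is.null(multipliers)) {
    multipliers <- switch(kind,
      none = c(IN = 1, SN = 1, ST = 1, IT = 1),
      TMB = {
        m <- c(IN = 1, SN = 1, ST = 1, IT = 1)
        m[quadrant_of_angle(site_angle)] <- tmb_multiplier
        m
      },
      AIT = c(IN = 2.00, SN = 1.75, ST = 1.19, IT = 1.40)
    )
  } else {
    multipliers <- multipliers[QUADRANTS]
  }
  if (any(!is.finite(multipliers)) || any(multipliers < 0)) {
    stop_difcanal("quadrant multipliers must be finite and >= 0",
                  "invalid_input")
  }
  if (kind == "none" && any(multipliers != 1)) {
    stop_difcanal("kind = \"none\" requires all multipliers equal to 1",
                  "invalid_input")
  }
  structure(
    list(kind = kind, site_angle = site_angle,
         quadrant_multipliers = multipliers),
    class = "surgery_effect"
  )
}

#' Apply a surgical effect to a baseline flow map
#'
#' Scales each quadrant's baseline fraction by the effect's multiplier. The
#' result represents (possibly enhanced) post-surgical flow and is not
#' renormalized.
#'
#' @param flow A baseline [flow_map()] (fractions summing to 1).
#' @param effect A [surgery_effect()].
#' @return A [flow_map()] of post-surgical relative flows.
#' @export
apply_surgery <- function(flow, effect) {
  stopifnot(inherits(flow, "flow_map"), inherits(effect, "surgery_effect"))
  if (abs(sum(flow) - 1) > 1e-6) {
    stop_difcanal("`flow` must be a baseline map with fractions summing to 1",
                  "invalid_input")
  }
  out <- unclass(flow) * effect$quadrant_multipliers[names(flow)]
  structure(out, focal_site_angle = effect$site_angle, class = "flow_map")
}

#' Acquisition configuration
#'
#' Camera and timing parameters of one time lapse. Defaults mirror the
#' imaging protocol: a 15-minute lapse of 46 frames every 20 s at 580 x 610
#' resolution with a 14-bit payload.
#'
#' @param n_frames Number of frames (>= 2); default 46.
#' @param frame_interval_s Seconds between frames; default 20.
#' @param width,height Frame size in pixels; defaults 580 x 610.
#' @param bit_depth Payload bit depth; default 14.
#' @param noise_sd Additive Gaussian camera noise SD in intensity units;
#'   default 20.
#' @param background_level Camera offset in intensity units; default 200.
#' @param seed Optional RNG seed for reproducible rendering.
#' @return An `acquisition_config` object.
#' @export
acquisition_config <- function(n_frames = 46L, frame_interval_s = 20,
                               width = 580L, height = 610L,
                               bit_depth = 14L, noise_sd = 20,
                               background_level = 200, seed = NULL) {
  if (n_frames < 2) {
    stop_difcanal("`n_frames` must be >= 2", "insufficient_frames")
  }
  check_number(frame_interval_s, "frame_interval_s", 0, strict = TRUE)
  check_number(noise_sd, "noise_sd", 0)
  if (background_level < 0 || background_level >= 2^bit_depth) {
    stop_difcanal("`background_level` must lie in [0, 2^bit_depth)",
                  "invalid_input")
  }
  structure(
    list(n_frames = as.integer(n_frames), frame_interval_s = frame_interval_s,
         width = as.integer(width), height = as.integer(height),
         bit_depth = as.integer(bit_depth), noise_sd = noise_sd,
         background_level = background_level, seed = seed),
    class = "acquisition_config"
  )
}

#' Per-dye perfusion kinetics of the phantom
#'
#' The phantom's perilimbal band in quadrant `q` rises linearly after an
#' onset delay and saturates at a steady-state plateau:
#' \deqn{v_q(t) = \min\{s_q \max(0, t - d_q),\ P_q\}}
#' with slope \eqn{s_q = g \cdot f_q \cdot E}, plateau
#' \eqn{P_q = p \cdot f_q \cdot E} and onset
#' \eqn{d_q = o \cdot d_0 / (\epsilon + f_q)}, where \eqn{f_q} is the
#' quadrant's relative flow and \eqn{E} the dye's emission at its working
#' concentration ([dye_emission()]).
#'
#' Defaults are dye-specific: Texas red fills ~19% later than fluorescein,
#' rises more steeply early, and saturates at a lower plateau, which is what
#' produces the FU/TR quadrant ratio of about 1.56 at the fluorescein
#' half-maximum frame in control phantoms.
#'
#' @param onset_scale Dye-specific multiplier `o` on the onset delay.
#' @param slope_gain Slope gain `g` in 1/s.
#' @param plateau_gain Plateau gain `p` (dimensionless).
#' @param base_delay Base onset delay `d0` in seconds; default 20.
#' @param eps Regularizer in the onset law; default 0.05.
#' @return A `dye_kinetics` object.
#' @export
dye_kinetics <- function(onset_scale = 1, slope_gain = 0.012,
                         plateau_gain = 20, base_delay = 20, eps = 0.05) {
  check_number(onset_scale, "onset_scale", 0, strict = TRUE)
  check_number(slope_gain, "slope_gain", 0, strict = TRUE)
  check_number(plateau_gain, "plateau_gain", 0, strict = TRUE)
  check_number(base_delay, "base_delay", 0)
  check_number(eps, "eps", 0, strict = TRUE)
  structure(
    list(onset_scale = onset_scale, slope_gain = slope_gain,
         plateau_gain = plateau_gain, base_delay = base_delay, eps = eps),
    class = "dye_kinetics"
  )
}

#' Default kinetics for a dye
#'
#' @param dye_name `"FU"` or `"TR"`.
#' @return A [dye_kinetics()] object.
#' @export
default_kinetics <- function(dye_name) {
  switch(dye_name,
    FU = dye_kinetics(onset_scale = 1.00, slope_gain = 0.012,
                      plateau_gain = 20),
    TR = dye_kinetics(onset_scale = 1.19, slope_gain = 0.020,
                      plateau_gain = 3.065),
    dye_kinetics()
  )
}

#' Onset delay per quadrant
#'
#' `d_q = onset_scale * base_delay / (eps + f_q)`: quadrants with more flow
#' fill earlier.
#'
#' @param flow A [flow_map()].
#' @param kin A [dye_kinetics()].
#' @param delay_jitter Scalar multiplier (per-eye variability); default 1.
#' @return Named numeric vector of delays in seconds.
#' @export
onset_delay <- function(flow, kin, delay_jitter = 1) {
  kin$onset_scale * delay_jitter * kin$base_delay / (kin$eps + unclass(flow))
}

#' Noiseless quadrant ramp (closed form)
#'
#' The exact expected perilimbal-band camera count of one quadrant at time
#' `t`: background plus the delayed, plateau-limited linear rise, rounded to
#' integer counts and clamped to the bit-depth range -- precisely what
#' [render_timelapse()] paints into that quadrant's band before noise.
#'
#' @param t Time(s) in seconds.
#' @param flow_frac Quadrant relative flow fraction.
#' @param dye A [dye_physics()].
#' @param acq An [acquisition_config()].
#' @param kin A [dye_kinetics()]; defaults to the dye's defaults.
#' @param delay_jitter Onset delay multiplier; default 1.
#' @return Numeric vector of expected counts, same length as `t`.
#' @export
quadrant_ramp <- function(t, flow_frac, dye, acq,
                          kin = default_kinetics(dye$name),
                          delay_jitter = 1) {
  E <- dye_emission(dye)
  d <- kin$onset_scale * delay_jitter * kin$base_delay / (kin$eps + flow_frac)
  v <- pmin(kin$slope_gain * flow_frac * E * pmax(0, t - d),
            kin$plateau_gain * flow_frac * E)
  pmin(pmax(round(acq$background_level + v), 0), 2^acq$bit_depth - 1)
}

#' Render a synthetic canalogram time lapse
#'
#' Paints, for every frame: the camera background everywhere; a uniform
#' anterior-chamber disc inside the limbus at the dye's working-concentration
#' emission (the chamber fills with perfused dye); and, in each perilimbal
#' quadrant band, the delayed linear-rise-to-plateau kinetics of
#' [quadrant_ramp()]. Additive Gaussian noise of SD `acq$noise_sd` is then
#' applied and values are rounded and clamped to `[0, 2^bit_depth - 1]`.
#' Rendering is bit-reproducible for a fixed `acq$seed`.
#'
#' @param geom An [eye_geometry()]; must fit inside the frame.
#' @param flow A [flow_map()] of relative quadrant flows.
#' @param dye A [dye_physics()].
#' @param acq An [acquisition_config()]; frame size must match `geom`.
#' @param kin A [dye_kinetics()]; defaults to the dye's defaults.
#' @param delay_jitter Scalar onset-delay multiplier; default 1.
#' @param chamber Render the anterior-chamber disc? Default `TRUE`.
#' @return A [timelapse()] carrying the ground truth in `$meta`.
#' @export
render_timelapse <- function(geom, flow, dye, acq,
                             kin = default_kinetics(dye$name),
                             delay_jitter = 1, chamber = TRUE) {
  stopifnot(inherits(flow, "flow_map"), inherits(dye, "dye_physics"),
            inherits(acq, "acquisition_config"))
  if (geom$width != acq$width || geom$height != acq$height) {
    stop_difcanal("geometry frame size does not match acquisition config",
                  "invalid_geometry")
  }
  validate_geometry_fits(geom)
  if (!is.null(acq$seed)) set.seed(acq$seed)
  lab <- quadrant_label_matrix(geom)
  band_idx <- lapply(seq_along(QUADRANTS), function(i) which(lab == i))
  disc_idx <- which(lab == -1L)
  maxval <- 2^acq$bit_depth - 1
  E <- dye_emission(dye)
  tt <- (seq_len(acq$n_frames) - 1) * acq$frame_interval_s
  f <- unclass(flow)
  d <- onset_delay(flow, kin, delay_jitter)
  slope <- kin$slope_gain * f * E
  plateau <- kin$plateau_gain * f * E
  npx <- acq$height * acq$width
  frames <- array(0L, dim = c(acq$height, acq$width, acq$n_frames))
  for (k in seq_len(acq$n_frames)) {
    img <- matrix(acq$background_level, acq$height, acq$width)
    if (chamber && length(disc_idx)) img[disc_idx] <- acq$background_level + E
    v <- pmin(slope * pmax(0, tt[k] - d), plateau)
    for (i in seq_along(band_idx)) {
      img[band_idx[[i]]] <- img[band_idx[[i]]] + v[i]
    }
    if (acq$noise_sd > 0) img <- img + rnorm(npx, 0, acq$noise_sd)
    frames[, , k] <- as.integer(pmin(pmax(round(img), 0), maxval))
  }
  timelapse(frames,
    frame_interval_s = acq$frame_interval_s,
    dye_label = dye$name,
    bit_depth = acq$bit_depth,
    meta = list(
      ground_truth = list(
        flow = as.list(unclass(flow)),
        delays_s = as.list(d),
        dye = dye$name,
        noise_sd = acq$noise_sd
      )
    )
  )
}

#' Default full-frame phantom geometry
#'
#' An eye centered in the default 580 x 610 frame with a 180 px limbus and
#' the default 1.5x perilimbal annulus.
#'
#' @param acq An [acquisition_config()].
#' @param laterality `"OD"` or `"OS"`.
#' @return An [eye_geometry()].
#' @export
default_geometry <- function(acq = acquisition_config(),
                             laterality = "OD") {
  eye_geometry(
    width = acq$width, height = acq$height,
    limbus_radius = round(min(acq$width, acq$height) * 0.31),
    laterality = laterality
  )
}

#' Simulate one paired-dye phantom eye
#'
#' Generates the FU (pre-surgical) and TR (post-surgical) time lapses of one
#' eye, with per-eye biological variability: quadrant flow fractions are
#' log-normally jittered around the baseline map and renormalized, and each
#' dye's onset delay receives an independent log-normal jitter (so FU/TR
#' filling-time differences vary between eyes, as between real specimens).
#' The surgical effect acts on the TR (second-dye) lapse only.
#'
#' @param seed Integer seed controlling all randomness for this eye.
#' @param effect A [surgery_effect()]; default none (control eye).
#' @param geom An [eye_geometry()]; default [default_geometry()].
#' @param acq An [acquisition_config()].
#' @param fu,tr [dye_physics()] objects for the two dyes.
#' @param flow Baseline [flow_map()]; default [control_flow_map()].
#' @param flow_jitter_sd Log-scale SD of per-quadrant flow jitter;
#'   default 0.10.
#' @param onset_jitter_sd Log-scale SD of per-dye onset jitter;
#'   default 0.20.
#' @return A `phantom_eye` list with elements `fu`, `tr` ([timelapse()]s),
#'   `geom`, and `truth` (jittered baseline flow, post-surgical flow,
#'   effect kind).
#' @export
simulate_eye <- function(seed, effect = surgery_effect("none"),
                         geom = default_geometry(acq), acq = acquisition_config(),
                         fu = fu_dye(), tr = tr_dye(),
                         flow = control_flow_map(),
                         flow_jitter_sd = 0.10, onset_jitter_sd = 0.20) {
  set.seed(seed)
  f <- unclass(flow) * exp(rnorm(4, 0, flow_jitter_sd))
  f <- f / sum(f)
  base <- flow_map(f[["IN"]], f[["SN"]], f[["ST"]], f[["IT"]])
  jit_fu <- exp(rnorm(1, 0, onset_jitter_sd))
  jit_tr <- exp(rnorm(1, 0, onset_jitter_sd))
  post <- apply_surgery(base, effect)
  fu_lapse <- render_timelapse(geom, base, fu, acq, delay_jitter = jit_fu)
  tr_lapse <- render_timelapse(geom, post, tr, acq, delay_jitter = jit_tr)
  structure(
    list(
      fu = fu_lapse, tr = tr_lapse, geom = geom,
      truth = list(flow = base, post_flow = post, effect = effect$kind,
                   multipliers = effect$quadrant_multipliers,
                   delay_jitter = c(FU = jit_fu, TR = jit_tr), seed = seed)
    ),
    class = "phantom_eye"
  )
}

#' Simulate a control cohort and collect matched quadrant intensities
#'
#' Streams `n_eyes` control phantoms (no surgery, alternating OD/OS as in a
#' paired-eye harvest), measures each pair at the fluorescein half-maximum
#' frame, and returns the calibration table without retaining the image
#' stacks.
#'
#' @param n_eyes Number of control eyes; default 8.
#' @param seed Base seed; eye `i` uses `seed + i`.
#' @param acq An [acquisition_config()].
#' @param geom_fn Function `(acq, laterality)` building each eye's
#'   geometry; default [default_geometry()].
#' @param ... Passed on to [simulate_eye()].
#' @return Tibble with columns `eye`, `laterality`, `quadrant`, `frame`,
#'   `fu`, `tr` -- the input expected by [estimate_normalization()].
#' @export
simulate_control_pairs <- function(n_eyes = 8, seed = 1,
                                   acq = acquisition_config(),
                                   geom_fn = default_geometry, ...) {
  purrr::map_dfr(seq_len(n_eyes), function(i) {
    lat <- if (i %% 2 == 1) "OD" else "OS"
    geom <- geom_fn(acq, laterality = lat)
    eye <- simulate_eye(seed + i, geom = geom, acq = acq, ...)
    dplyr::mutate(
      matched_quadrant_intensities(eye$fu, eye$tr, geom),
      eye = i, laterality = lat, .before = 1
    )
  })
}
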