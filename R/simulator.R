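# Synthetic acquisition generator standing in for the linac + EPID: renders
# rolling-shutter BB-phantom frames along a gantry trajectory, emits
# jittered ~4 Hz machine messages, injects panel sag / gain nonuniformity /
# noise, and exports per-frame ground truth. The rolling shutter is
# implemented per native column, independently of the correction code it is
# used to validate.

#' Simulation configuration
#'
#' Defaults reproduce the end-to-end validation layout: an 8-mm ball
#' bearing offset 10 cm laterally and 5 cm longitudinally from the plan
#' isocenter, a 24 x 24 cm field, clockwise 360-degree arcs, machine
#' messages at 4 Hz with uniform +/-50 ms timestamp jitter.
#'
#' @param bb_center_cm BB center in room coordinates, cm.
#' @param bb_diameter_mm BB diameter, mm.
#' @param trajectory list: `start_deg`, and `segments`, a list of
#'   `list(speed_dps, duration_s)` (signed speed; positive = clockwise,
#'   increasing gantry angle).
#' @param message_rate_hz machine-message rate.
#' @param message_jitter_s uniform half-width of the message timestamp
#'   jitter, seconds.
#' @param noise_sigma Gaussian intensity noise, 16-bit counts.
#' @param sag list `amp_ab_px`, `phase_ab_deg`, `amp_gt_px`,
#'   `phase_gt_deg`: sinusoidal panel displacement
#'   `amp * sin(theta + phase)` per axis, native pixels.
#' @param gain_field multiplicative detector nonuniformity (matrix matching
#'   the panel, or `NULL` for unity).
#' @param field_mm open-field size at isocenter scale, mm (x, y).
#' @param field_intensity,bg_intensity,dark_level photometric levels,
#'   16-bit counts.
#' @param bb_attenuation fractional intensity drop inside the BB shadow.
#' @param seed integer; fully determines all randomness.
#' @param geom a [linac_geometry()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(bb_center_cm = c(-10, -5, 0),
                       bb_diameter_mm = 8,
                       trajectory = list(start_deg = 180,
                                         segments = list(list(speed_dps = 1.5,
                                                              duration_s = 240))),
                       message_rate_hz = 4,
                       message_jitter_s = 0.05,
                       noise_sigma = 200,
                       sag = list(amp_ab_px = 0, phase_ab_deg = 0,
                                  amp_gt_px = 0, phase_gt_deg = 0),
                       gain_field = NULL,
                       field_mm = c(240, 240),
                       field_intensity = 40000, bg_intensity = 2000,
                       dark_level = 1000, bb_attenuation = 0.4,
                       seed = 1L, geom = linac_geometry()) {
  speeds <- vapply(trajectory$segments, `[[`, numeric(1), "speed_dps")
  if (any(abs(speeds) > 4.8 + 1e-9))
    warning("gantry speed outside the clinical 4.8 deg/s envelope")
  cfg <- list(bb_center_cm = bb_center_cm, bb_diameter_mm = bb_diameter_mm,
              trajectory = trajectory, message_rate_hz = message_rate_hz,
              message_jitter_s = message_jitter_s, noise_sigma = noise_sigma,
              sag = sag, gain_field = gain_field, field_mm = field_mm,
              field_intensity = field_intensity, bg_intensity = bg_intensity,
              dark_level = dark_level, bb_attenuation = bb_attenuation,
              seed = as.integer(seed), geom = geom)
  class(cfg) <- "sim_config"
  cfg
}

#' Validation and calibration presets
#'
#' `"bb-validation"` reproduces the end-to-end test layout (BB offset
#' (-10, -5, 0) cm from the isocenter, 24 x 24 cm field, clockwise full
#' arc at `speed_dps`); `"panel-calibration"` puts the BB at the isocenter
#' with a 10 x 10 cm field and an ideal (sag-free, noise-free, jitter-free)
#' chain unless overridden.
#'
#' @param name preset name.
#' @param speed_dps gantry speed, degrees per second (sign = direction).
#' @param seed integer seed.
#' @param ... overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_preset <- function(name = c("bb-validation", "panel-calibration"),
                       speed_dps = 1.5, seed = 1L, ...) {
  name <- match.arg(name)
  dur <- 360 / abs(speed_dps)
  traj <- list(start_deg = 180,
               segments = list(list(speed_dps = speed_dps, duration_s = dur)))
  if (name == "bb-validation") {
    sim_config(trajectory = traj, seed = seed, ...)
  } else {
    sim_config(bb_center_cm = c(0, 0, 0), field_mm = c(100, 100),
               trajectory = traj, message_jitter_s = 0, noise_sigma = 0,
               seed = seed, ...)
  }
}

#' True gantry angle of a trajectory at time t
#'
#' Piecewise-constant-speed trajectory starting at `t = 0`; times beyond
#' the last segment hold the final angle.
#'
#' @param cfg a [sim_config()].
#' @param t time(s), seconds.
#' @return Gantry angle(s) in `[0, 360)`.
#' @export
trajectory_angle <- function(cfg, t) {
  tr <- cfg$trajectory
  segs <- tr$segments
  durs <- vapply(segs, `[[`, numeric(1), "duration_s")
  speeds <- vapply(segs, `[[`, numeric(1), "speed_dps")
  starts <- c(0, cumsum(durs))
  base <- c(0, cumsum(speeds * durs))
  ang <- rep(tr$start_deg + base[length(base)], length(t))
  tt <- pmax(t, 0)
  for (i in seq_along(segs)) {
    inseg <- tt >= starts[i] & tt < starts[i + 1]
    ang[inseg] <- tr$start_deg + base[i] + speeds[i] * (tt[inseg] - starts[i])
  }
  ang[tt < 0] <- tr$start_deg
  wrap_angle(ang)
}

trajectory_duration <- function(cfg) {
  sum(vapply(cfg$trajectory$segments, `[[`, numeric(1), "duration_s"))
}

#' Simulate the machine message stream
#'
#' Angles are sampled exactly from the trajectory at the true emission
#' times; the reported timestamps carry uniform jitter of half-width
#' `cfg$message_jitter_s`, modeling the imprecise receive-time stamping of
#' the real stream (the angle values themselves stay exact).
#'
#' @param cfg a [sim_config()].
#' @return A [machine_messages()] data frame, with the true emission times
#'   in attribute `"true_time_s"`.
#' @export
simulate_messages <- function(cfg) {
  set.seed(cfg$seed + 1L)
  dt <- 1 / cfg$message_rate_hz
  if (2 * cfg$message_jitter_s >= dt)
    stop("jitter half-width >= message interval: stream order not guaranteed")
  t_true <- seq(0, trajectory_duration(cfg), by = dt)
  rep_ts <- t_true + stats::runif(length(t_true), -cfg$message_jitter_s,
                                  cfg$message_jitter_s)
  if (is.unsorted(rep_ts, strictly = TRUE))
    stop("jitter broke message monotonicity")
  msg <- machine_messages(rep_ts, trajectory_angle(cfg, t_true))
  attr(msg, "true_time_s") <- t_true
  msg
}

# vectorized projection of one room point over a vector of angles:
# returns list(u_cm, v_cm, scale)
project_point_vec <- function(point_cm, theta_deg, geom) {
  th <- wrap_angle(theta_deg) * pi / 180
  sad <- geom$sad_cm
  o <- as.numeric(point_cm)
  sx <- sad * sin(th); sz <- sad * cos(th)
  denom <- sad^2 - (sx * o[1] + sz * o[3])
  t <- sad^2 / denom
  px <- sx + t * (o[1] - sx)
  py <- t * o[2]
  pz <- sz + t * (o[3] - sz)
  list(u_cm = px * cos(th) - pz * sin(th), v_cm = py, scale = t)
}

sag_at <- function(cfg, theta_deg) {
  s <- cfg$sag
  th <- theta_deg * pi / 180
  c(dx = s$amp_ab_px * sin(th + s$phase_ab_deg * pi / 180),
    dy = s$amp_gt_px * sin(th + s$phase_gt_deg * pi / 180))
}

#' Render one rolling-shutter EPID frame
#'
#' Each native column is rendered with the scene geometry at its own
#' readout time (the true trajectory, no jitter): the BB is drawn as an
#' attenuated disk at its projected position for that column's gantry
#' angle, with the projection magnification of its room position and a
#' soft one-pixel edge. The static field borders, panel sag (a whole-frame
#' translation evaluated at the frame-timestamp angle), multiplicative
#' gain field, dark level and Gaussian noise are then applied and the
#' result clipped to 16 bits.
#'
#' Noise is drawn from the current RNG state; run inside a seeded context
#' ([simulate_arc()] seeds once per arc) for reproducible sequences.
#'
#' @param cfg a [sim_config()].
#' @param ts frame timestamp (readout completion), seconds.
#' @return An [epid_frame()].
#' @export
render_frame <- function(cfg, ts) {
  geom <- cfg$geom
  n <- geom$panel_matrix
  ctr <- (n - 1) / 2
  cols <- 0:(n - 1)
  t_c <- column_readout_time(ts, cols, geom)
  th_c <- trajectory_angle(cfg, t_c)
  pr <- project_point_vec(cfg$bb_center_cm, th_c, geom)
  sag <- sag_at(cfg, trajectory_angle(cfg, ts))
  col_bb <- ctr + pr$u_cm * 10 / geom$pixel_iso_mm + sag[1]
  row_bb <- ctr + pr$v_cm * 10 / geom$pixel_iso_mm + sag[2]
  r_bb <- (cfg$bb_diameter_mm / 2) * pr$scale / geom$pixel_iso_mm

  img <- matrix(cfg$bg_intensity, n, n)
  half_c <- cfg$field_mm[1] / 2 / geom$pixel_iso_mm
  half_r <- cfg$field_mm[2] / 2 / geom$pixel_iso_mm
  fc <- max(1, ceiling(ctr - half_c + sag[1]) + 1):
        min(n, floor(ctr + half_c + sag[1]) + 1)
  fr <- max(1, ceiling(ctr - half_r + sag[2]) + 1):
        min(n, floor(ctr + half_r + sag[2]) + 1)
  img[fr, fc] <- cfg$field_intensity

  dcol <- cols - col_bb
  active <- which(abs(dcol) < r_bb + 1)   # 1-based index; column = active - 1
  for (ci in active) {
    h2 <- r_bb[ci]^2 - dcol[ci]^2
    if (h2 <= 0) next
    h <- sqrt(h2)
    lo <- max(0, floor(row_bb[ci] - h - 1)); hi <- min(n - 1, ceiling(row_bb[ci] + h + 1))
    if (lo > hi) next
    rr <- lo:hi
    # soft edge: attenuation ramps over ~1 px at the chord ends
    cov <- pmin(pmax(h - abs(rr - row_bb[ci]) + 0.5, 0), 1)
    att <- 1 - cfg$bb_attenuation * cov
    img[rr + 1, ci] <- img[rr + 1, ci] * att
  }
  if (!is.null(cfg$gain_field)) img <- img * cfg$gain_field
  img <- img + cfg$dark_level
  if (cfg$noise_sigma > 0)
    img <- img + matrix(stats::rnorm(n * n, 0, cfg$noise_sigma), n, n)
  img <- round(pmin(pmax(img, 0), 65535))
  epid_frame(img, ts)
}

#' Matched gain calibration for a simulated acquisition
#'
#' The dark frame at the configured dark level and a full-panel flood at
#' the field intensity times the gain field: exactly what the dark/gain
#' correction chain expects.
#'
#' @param cfg a [sim_config()].
#' @return A [gain_calibration()].
#' @export
sim_calibration <- function(cfg) {
  n <- cfg$geom$panel_matrix
  dark <- matrix(cfg$dark_level, n, n)
  gf <- if (is.null(cfg$gain_field)) 1 else cfg$gain_field
  flood <- dark + cfg$field_intensity * gf
  gain_calibration(dark, list(list(dose_rate = 400, pixels = flood)))
}

#' Simulate a full arc acquisition
#'
#' Frames at the integration-time cadence (optionally strided to thin the
#' sequence while spanning the same arc), the jittered message stream, and
#' complete ground truth: per frame the frame-timestamp angle, the angle
#' and native-pixel BB centroid at the BB's own readout column (the
#' rolling-shutter fixed point), and per message the true emission time.
#'
#' @param cfg a [sim_config()].
#' @param frame_stride keep every `frame_stride`-th frame (default 1).
#' @param out_dir if non-`NULL`, write frames (`frame_%04d.raw` +
#'   `frames.jsonl` timestamp sidecar), `messages.csv` and
#'   `ground_truth.json` there.
#' @return A list of class `sim_arc`: `frames` (list of [epid_frame()]),
#'   `messages`, `truth` (data frame: `ts`, `theta_ts_deg`,
#'   `theta_bb_deg`, `bb_column_native`, `bb_row_native`), `cfg`.
#' @export
simulate_arc <- function(cfg, frame_stride = 1L, out_dir = NULL) {
  geom <- cfg$geom
  msgs <- simulate_messages(cfg)
  T_int <- geom$integration_time_s
  ts_all <- seq(T_int, trajectory_duration(cfg), by = T_int)
  ts_all <- ts_all[seq(1, length(ts_all), by = frame_stride)]
  set.seed(cfg$seed + 2L)
  frames <- lapply(ts_all, function(ts) render_frame(cfg, ts))
  truth <- do.call(rbind, lapply(ts_all, function(ts) {
    th_ts <- trajectory_angle(cfg, ts)
    ctr <- (geom$panel_matrix - 1) / 2
    # rolling-shutter fixed point: column c with c = col_bb(theta(t(c)))
    cc <- ctr + project_point_vec(cfg$bb_center_cm, th_ts, geom)$u_cm * 10 /
      geom$pixel_iso_mm
    for (i in 1:4) {
      th <- trajectory_angle(cfg, column_readout_time(
        ts, min(max(cc, 0), geom$panel_matrix - 1), geom))
      pr <- project_point_vec(cfg$bb_center_cm, th, geom)
      cc <- ctr + pr$u_cm * 10 / geom$pixel_iso_mm
    }
    sag <- sag_at(cfg, th_ts)
    data.frame(ts = ts, theta_ts_deg = th_ts, theta_bb_deg = th,
               bb_column_native = cc + sag[1],
               bb_row_native = ctr + pr$v_cm * 10 / geom$pixel_iso_mm + sag[2])
  }))
  out <- list(frames = frames, messages = msgs, truth = truth, cfg = cfg)
  class(out) <- "sim_arc"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    sidecar <- file(file.path(out_dir, "frames.jsonl"), "w")
    for (i in seq_along(frames)) {
      fn <- sprintf("frame_%04d.raw", i)
      write_frame_raw(frames[[i]], file.path(out_dir, fn))
      writeLines(jsonlite::toJSON(list(file = fn, ts = frames[[i]]$ts),
                                  auto_unbox = TRUE, digits = NA), sidecar)
    }
    close(sidecar)
    write_messages(msgs, file.path(out_dir, "messages.csv"))
    jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                         digits = NA)
  }
  out
}

#' Matching DICOM fixture suite for a simulated arc
#'
#' Writes the CT / RTSTRUCT / RTPLAN triplet whose geometry corresponds to
#' a simulation config: the BB contoured on a fine CT lattice around its
#' room position, the plan isocenter at the room origin, and one arc beam
#' per trajectory segment.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory.
#' @param ct_spacing_mm CT voxel spacing `c(row, col, slice)`, mm.
#' @return The [write_fixture_suite()] file list, invisibly.
#' @export
sim_fixture_suite <- function(cfg, dir, ct_spacing_mm = c(0.5, 0.5, 1.0)) {
  iso <- c(0, 0, 50)   # arbitrary patient-space isocenter
  r <- cfg$bb_diameter_mm / 2
  # room -> patient (inverse of patient_to_room, identity orientation)
  ctr_pat <- c(iso[1] + 10 * cfg$bb_center_cm[1],
               iso[2] - 10 * cfg$bb_center_cm[3],
               iso[3] + 10 * cfg$bb_center_cm[2])
  pad <- c(12, 12, 9)
  dims <- ceiling(2 * pad / ct_spacing_mm[c(1, 2, 3)])
  origin <- ctr_pat - (dims[c(2, 1, 3)] - 1) / 2 * ct_spacing_mm[c(2, 1, 3)]
  segs <- cfg$trajectory$segments
  beams <- lapply(seq_along(segs), function(i) {
    s <- segs[[i]]
    list(name = paste0("ARC", i), start_deg = cfg$trajectory$start_deg,
         span_deg = abs(s$speed_dps) * s$duration_s,
         direction = if (s$speed_dps >= 0) "CW" else "CC",
         speed_dps = abs(s$speed_dps),
         field_mm = cfg$field_mm, collimator_deg = 0, n_ctrl = 24,
         energy = 6)
  })
  spec <- list(
    ct = list(dims = dims, spacing = ct_spacing_mm, origin = origin),
    rois = list(list(name = "BB", color = c(255, 0, 0), shape = "sphere",
                     center = ctr_pat, radius_mm = r)),
    isocenter = iso, beams = beams, seed = cfg$seed)
  invisible(write_fixture_suite(spec, dir))
}
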