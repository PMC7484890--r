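# Offline replay and evaluation: per-frame angle assignment + overlay
# lookup, the retrospective accuracy analysis with its lag/lead sign
# convention, and fiducial-visibility bookkeeping.

#' Retrospective projection-accuracy analysis
#'
#' For every frame: preprocess, detect the BB centroid, assign the
#' readout-time-corrected gantry angle, look up the precomputed contour,
#' and difference the contour centroid against the detected BB centroid at
#' isocenter scale (binned pixel = 0.5 mm). In the lateral (AB) direction
#' the polarity of the error is inverted for positive gantry angles
#' (signed angle in (0, 180)), so that a negative adjusted error always
#' means the contour lags behind the BB and a positive one that it runs
#' ahead, independent of which side of the arc the frame came from; the
#' mean adjusted error then isolates a systematic timing or encoder offset.
#'
#' @param arc a [simulate_arc()] result (frames + messages), or a list
#'   with `frames` and `messages`.
#' @param set a [precompute_set()] result containing `roi_name`.
#' @param cal a [gain_calibration()].
#' @param table a [panel_correction_table()] or `NULL`.
#' @param roi_name ROI to evaluate.
#' @param geom a [linac_geometry()].
#' @return An object of class `accuracy_report`: `frames` (per-frame data
#'   frame with `ts`, `theta_assigned_deg`, `ab_error_mm`, `gt_error_mm`,
#'   `ab_error_adj_mm`), `summary` (`mu_ab_mm`, `sigma_ab_mm`, `mu_gt_mm`,
#'   `sigma_gt_mm`, `n_frames`, `n_excluded`).
#' @export
evaluate_accuracy <- function(arc, set, cal, table = NULL,
                              roi_name = "BB", geom = linac_geometry()) {
  rows <- list()
  excluded <- 0L
  for (fr in arc$frames) {
    th_ts <- interpolate_angle(arc$messages, fr$ts)
    proc <- preprocess(fr, cal, table, th_ts, geom = geom)
    bb <- tryCatch(detect_bb_centroid(proc, native = FALSE, geom = geom),
                   error = function(e) NULL)
    if (is.null(bb)) { excluded <- excluded + 1L; next }
    asg <- assign_roi_angle(fr$ts, arc$messages, set, roi_name, geom)
    ov <- lookup_overlay(set, roi_name, asg$theta_deg)
    if (is.null(ov$centroid)) { excluded <- excluded + 1L; next }
    mm_per_px <- 2 * geom$pixel_iso_mm
    ab <- (ov$centroid[["column"]] - bb[["column"]]) * mm_per_px
    gt <- (ov$centroid[["row"]] - bb[["row"]]) * mm_per_px
    th_s <- signed_angle(asg$theta_deg)
    ab_adj <- if (th_s > 0 && th_s < 180) -ab else ab
    rows[[length(rows) + 1]] <- data.frame(
      ts = fr$ts, theta_assigned_deg = asg$theta_deg,
      ab_error_mm = ab, gt_error_mm = gt, ab_error_adj_mm = ab_adj)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ts = numeric(0), theta_assigned_deg = numeric(0),
               ab_error_mm = numeric(0), gt_error_mm = numeric(0),
               ab_error_adj_mm = numeric(0))
  out <- list(frames = df,
              summary = list(
                mu_ab_mm = mean(df$ab_error_adj_mm),
                sigma_ab_mm = stats::sd(df$ab_error_adj_mm),
                mu_gt_mm = mean(df$gt_error_mm),
                sigma_gt_mm = stats::sd(df$gt_error_mm),
                n_frames = nrow(df), n_excluded = excluded))
  class(out) <- "accuracy_report"
  out
}

#' @export
print.accuracy_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<accuracy_report> %d frames (%d excluded)\n  AB: mu %+.3f mm, sigma %.3f mm (polarity-adjusted)\n  GT: mu %+.3f mm, sigma %.3f mm\n",
    s$n_frames, s$n_excluded, s$mu_ab_mm, s$sigma_ab_mm,
    s$mu_gt_mm, s$sigma_gt_mm))
  invisible(x)
}

#' Count markers visible inside the open aperture
#'
#' A marker is "visible" when at least `threshold` of its projected disk
#' lies inside the open field. The disk is rasterized at binned resolution
#' and tested against the centered rectangular aperture.
#'
#' @param markers_cm list of room points (cm), one per marker.
#' @param theta_deg gantry angle of the frame.
#' @param field_mm open aperture size at isocenter scale, mm `(x, y)`;
#'   or an explicit logical aperture mask at binned resolution.
#' @param marker_diameter_mm physical marker diameter, mm.
#' @param threshold visible-area fraction required.
#' @param geom a [linac_geometry()].
#' @return Integer count of visible markers.
#' @export
count_visible_markers <- function(markers_cm, theta_deg, field_mm = c(240, 240),
                                  marker_diameter_mm = 1,
                                  threshold = 0.5, geom = linac_geometry()) {
  nb <- geom$panel_matrix / 2
  ctr <- (nb - 1) / 2
  pitch <- 2 * geom$pixel_iso_mm
  if (is.matrix(field_mm)) {
    mask <- field_mm
  } else {
    mask <- matrix(FALSE, nb, nb)
    hc <- field_mm[1] / 2 / pitch; hr <- field_mm[2] / 2 / pitch
    cc <- max(1, ceiling(ctr - hc) + 1):min(nb, floor(ctr + hc) + 1)
    rr <- max(1, ceiling(ctr - hr) + 1):min(nb, floor(ctr + hr) + 1)
    mask[rr, cc] <- TRUE
  }
  n_vis <- 0L
  for (mk in markers_cm) {
    pr <- project_point_vec(mk, theta_deg, geom)
    col0 <- ctr + pr$u_cm * 10 / pitch
    row0 <- ctr + pr$v_cm * 10 / pitch
    r_px <- max((marker_diameter_mm / 2) * pr$scale / pitch, 0.75)
    cc <- floor(col0 - r_px):ceiling(col0 + r_px)
    rr <- floor(row0 - r_px):ceiling(row0 + r_px)
    g <- expand.grid(r = rr, c = cc)
    ind <- (g$c - col0)^2 + (g$r - row0)^2 <= r_px^2
    g <- g[ind, , drop = FALSE]
    if (nrow(g) == 0) next
    inb <- g$r >= 0 & g$r < nb & g$c >= 0 & g$c < nb
    inside <- logical(nrow(g))
    inside[inb] <- mask[cbind(g$r[inb] + 1, g$c[inb] + 1)]
    if (mean(inside) >= threshold) n_vis <- n_vis + 1L
  }
  n_vis
}

#' Visibility periods, frequency and fraction of treatment
#'
#' From a per-frame visible-marker count series: periods of consecutive
#' frames with at least `min_markers` visible, the elapsed-time frequency
#' (inverse of the time between the first frames of consecutive periods),
#' mean period duration, and the fraction of frames with visibility.
#'
#' @param counts integer vector, visible markers per frame.
#' @param ts frame timestamps, seconds.
#' @param min_markers visibility requires at least this many markers.
#' @return An object of class `visibility_trace`: `counts`, `periods`
#'   (data frame `start_ts`, `end_ts`, `n_frames`, `duration_s`),
#'   `frequency_hz` (mean; `NA` with fewer than two periods),
#'   `mean_duration_s`, `fraction_visible`.
#' @export
visibility_trace <- function(counts, ts, min_markers = 1L) {
  stopifnot(length(counts) == length(ts))
  vis <- counts >= min_markers
  if (length(vis) == 0 || !any(vis)) {
    return(structure(list(counts = counts,
                          periods = data.frame(start_ts = numeric(0),
                                               end_ts = numeric(0),
                                               n_frames = integer(0),
                                               duration_s = numeric(0)),
                          frequency_hz = NA_real_, mean_duration_s = NA_real_,
                          fraction_visible = 0),
                     class = "visibility_trace"))
  }
  r <- rle(vis)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  frame_dt <- if (length(ts) > 1) stats::median(diff(ts)) else 0
  periods <- data.frame(start_ts = ts[starts[keep]], end_ts = ts[ends[keep]],
                        n_frames = r$lengths[keep])
  periods$duration_s <- periods$n_frames * frame_dt
  freq <- if (nrow(periods) >= 2)
    mean(1 / diff(periods$start_ts)) else NA_real_
  structure(list(counts = counts, periods = periods, frequency_hz = freq,
                 mean_duration_s = mean(periods$duration_s),
                 fraction_visible = mean(vis)),
            class = "visibility_trace")
}

#' Offline replay of an acquisition with overlays
#'
#' Re-runs, frame by frame, the computation performed live during
#' delivery: preprocess, per-ROI readout-time angle assignment, overlay
#' lookup, histogram equalization, and contour rendering. One PNG per
#' frame plus a JSON-lines event log.
#'
#' @param arc a [simulate_arc()] result or equivalent list with `frames`
#'   and `messages`.
#' @param set a [precompute_set()] result.
#' @param cal a [gain_calibration()]; refusal with a message when missing.
#' @param table a [panel_correction_table()] or `NULL`.
#' @param out_dir output directory for `frame_%04d.png` and
#'   `replay_log.jsonl`.
#' @param roi_names ROIs to display (default: all in the set).
#' @param threshold_fraction equalization threshold.
#' @param geom a [linac_geometry()].
#' @return Invisibly, the event log data frame (`frame`, `ts`, `roi`,
#'   `theta_assigned_deg`, `overlay_theta_deg`).
#' @export
replay <- function(arc, set, cal, table = NULL, out_dir,
                   roi_names = NULL, threshold_fraction = 0.70,
                   geom = linac_geometry()) {
  if (missing(cal) || is.null(cal))
    stop("gain calibration is required for replay; none provided")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(roi_names)) roi_names <- names(set$rois)
  log_con <- file(file.path(out_dir, "replay_log.jsonl"), "w")
  on.exit(close(log_con))
  logs <- list()
  for (i in seq_along(arc$frames)) {
    fr <- arc$frames[[i]]
    th_ts <- interpolate_angle(arc$messages, fr$ts)
    proc <- preprocess(fr, cal, table, th_ts, geom = geom)
    disp <- histogram_equalize(proc, threshold_fraction)
    ovs <- list()
    for (nm in roi_names) {
      asg <- assign_roi_angle(fr$ts, arc$messages, set, nm, geom)
      ov <- lookup_overlay(set, nm, asg$theta_deg)
      ovs[[nm]] <- ov
      row <- data.frame(frame = i, ts = fr$ts, roi = nm,
                        theta_assigned_deg = asg$theta_deg,
                        overlay_theta_deg = ov$theta_deg)
      logs[[length(logs) + 1]] <- row
      writeLines(jsonlite::toJSON(as.list(row), auto_unbox = TRUE,
                                  digits = NA), log_con)
    }
    img <- render_overlay(disp, ovs)
    png::writePNG(img, file.path(out_dir, sprintf("frame_%04d.png", i)))
  }
  invisible(do.call(rbind, logs))
}
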