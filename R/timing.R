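#' Column readout time of a rolling-shutter frame
#'
#' The flat panel is split laterally into two halves with independent
#' readout electronics. Both halves are read synchronously, column by
#' column, from the outside in: the A-side half starts at column 0 and ends
#' at column 511, the B-side half starts at column 1023 and ends at column
#' 512, both spanning one integration time. With `TS` the frame timestamp
#' (completion of the panel readout),
#'
#' `t(c) = TS - T + alpha_c * T / 511`,  `alpha_c = c` for `c` in 0..511 and
#' `alpha_c = 1023 - c` for `c` in 512..1023,
#'
#' with `T` the integration time (0.433 s by default).
#'
#' @param ts frame timestamp, seconds (monotone acquisition clock).
#' @param column native column index (or vector), 0..1023.
#' @param geom a [linac_geometry()].
#' @return Readout time(s) in seconds, within `[ts - T, ts]`.
#' @export
#' @examples
#' column_readout_time(10, 0)    # 10 - 0.433
#' column_readout_time(10, 511)  # 10
column_readout_time <- function(ts, column, geom = linac_geometry()) {
  n <- geom$panel_matrix
  if (any(column < 0 | column > n - 1))
    stop("column index out of range 0..", n - 1)
  column <- as.numeric(column)
  half <- n / 2
  alpha <- ifelse(column <= half - 1, column, n - 1 - column)
  ts - geom$integration_time_s +
    alpha * geom$integration_time_s / (half - 1)
}

#' Machine message stream constructor
#'
#' A data frame of timestamped machine-state samples as delivered by the
#' linac at roughly 4 Hz: timestamp (s), gantry angle (deg), state, dose
#' rate and nominal energy.
#'
#' @param timestamp_s numeric, strictly increasing.
#' @param gantry_deg gantry angles in `[0, 360)` (any real accepted).
#' @param state character linac state (e.g. "BEAM_ON").
#' @param dose_rate numeric, arbitrary units.
#' @param energy nominal energy, MV.
#' @return A `data.frame` of class `machine_messages`.
#' @export
machine_messages <- function(timestamp_s, gantry_deg,
                             state = "BEAM_ON", dose_rate = 400,
                             energy = 6) {
  stopifnot(length(timestamp_s) == length(gantry_deg))
  if (is.unsorted(timestamp_s, strictly = TRUE))
    stop("message timestamps must be strictly increasing")
  n <- length(timestamp_s)
  out <- data.frame(timestamp_s = timestamp_s,
                    gantry_deg = wrap_angle(gantry_deg),
                    state = rep_len(state, n), dose_rate = rep_len(dose_rate, n),
                    energy = rep_len(energy, n), stringsAsFactors = FALSE)
  class(out) <- c("machine_messages", "data.frame")
  out
}

#' Read / write a machine message stream as CSV
#'
#' Plain CSV with columns `timestamp_s, gantry_deg, state, dose_rate,
#' energy`; written and re-read bit-exactly (timestamps and angles with
#' full precision).
#'
#' @param messages a [machine_messages()] data frame.
#' @param path file path.
#' @return `read_messages` returns a `machine_messages` data frame.
#' @export
write_messages <- function(messages, path) {
  df <- as.data.frame(messages)
  df$timestamp_s <- sprintf("%.9f", df$timestamp_s)
  df$gantry_deg <- sprintf("%.9f", df$gantry_deg)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_messages
#' @export
read_messages <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  machine_messages(df$timestamp_s, df$gantry_deg, df$state,
                   df$dose_rate, df$energy)
}

# Unwrap a gantry-angle sequence to a continuous trace, assuming < 180 deg
# traveled between consecutive samples (safe at <= 4.8 deg/s and ~4 Hz).
unwrap_angles <- function(gantry_deg) {
  a <- wrap_angle(gantry_deg)
  if (length(a) < 2) return(a)
  d <- diff(a)
  d <- d - 360 * round(d / 360)
  a[1] + c(0, cumsum(d))
}

#' Interpolate the gantry angle at a time point
#'
#' Linear interpolation of the message-stream gantry angles on the
#' unwrapped angle (continuous across the 0/360 seam), reduced back to
#' `[0, 360)`. Times slightly outside the message coverage (up to one median
#' message interval) are clamped to the nearest end; beyond that an error is
#' raised.
#'
#' @param messages a [machine_messages()] data frame.
#' @param t query time(s), seconds.
#' @return Gantry angle(s) in `[0, 360)`.
#' @export
interpolate_angle <- function(messages, t) {
  if (NROW(messages) == 0) stop("empty message stream")
  ts <- messages$timestamp_s
  if (NROW(messages) == 1) return(rep(wrap_angle(messages$gantry_deg), length(t)))
  slack <- stats::median(diff(ts))
  if (any(t < ts[1] - slack | t > ts[length(ts)] + slack))
    stop("query time outside message coverage (beyond one message interval)")
  tq <- pmin(pmax(t, ts[1]), ts[length(ts)])
  un <- unwrap_angles(messages$gantry_deg)
  wrap_angle(stats::approx(ts, un, xout = tq)$y)
}

#' Assign a readout-time-corrected gantry angle to a frame for one ROI
#'
#' Because the panel is read column by column, the effective acquisition
#' time of an off-center ROI differs from the frame timestamp by up to one
#' integration time. The assignment is iterative: interpolate the angle at
#' the frame timestamp `TS`, read the centroid column of the ROI projection
#' at that angle, convert it to a native column, evaluate the column readout
#' time, and re-interpolate the angle at that time. One refinement step is
#' the default; `max_iter > 1` enables a fixed-point mode that stops when
#' the angle changes by less than `tol_deg`.
#'
#' @param ts frame timestamp, seconds.
#' @param messages a [machine_messages()] data frame.
#' @param set a projection set from [precompute_set()].
#' @param roi_name ROI to use for the centroid column.
#' @param geom a [linac_geometry()].
#' @param max_iter maximum refinement iterations (default 1).
#' @param tol_deg fixed-point stopping tolerance, degrees.
#' @return A list: `theta_deg` (assigned angle), `theta_ts_deg` (naive
#'   timestamp-interpolated angle), `column` (native centroid column used,
#'   `NA` if the overlay was empty), `t_s` (readout time used), `fallback`
#'   (`TRUE` if the overlay at the initial angle was empty and the naive
#'   angle was returned).
#' @export
assign_roi_angle <- function(ts, messages, set, roi_name,
                             geom = linac_geometry(),
                             max_iter = 1L, tol_deg = 0.05) {
  theta0 <- interpolate_angle(messages, ts)
  theta <- theta0
  col_native <- NA_real_
  t_used <- ts
  for (i in seq_len(max_iter)) {
    ov <- lookup_overlay(set, roi_name, theta)
    if (is.null(ov$centroid)) {
      return(list(theta_deg = theta0, theta_ts_deg = theta0,
                  column = NA_real_, t_s = ts, fallback = TRUE))
    }
    # binned centroid column -> native column (Eq. defined on native columns)
    col_native <- min(max(round(2 * ov$centroid[["column"]]), 0),
                      geom$panel_matrix - 1)
    t_used <- column_readout_time(ts, col_native, geom)
    theta_new <- interpolate_angle(messages, t_used)
    done <- abs(signed_angle(theta_new - theta)) < tol_deg
    theta <- theta_new
    if (done) break
  }
  list(theta_deg = theta, theta_ts_deg = theta0, column = col_native,
       t_s = t_used, fallback = FALSE)
}
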