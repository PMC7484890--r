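# Panel-position calibration: the ball bearing (BB) is fixed at the
# isocenter and imaged over full arcs; the gantry-angle-indexed offsets that
# bring its detected centroid back to the image center (511.5, 511.5 native)
# form the panel-position correction table applied during preprocessing.

# 8-neighborhood binary erosion (shrinks a mask by `iter` pixels)
erode_mask <- function(mask, iter = 1L) {
  n <- nrow(mask); m <- ncol(mask)
  for (it in seq_len(iter)) {
    pad <- matrix(FALSE, n + 2, m + 2)
    pad[2:(n + 1), 2:(m + 1)] <- mask
    mask <- pad[1:n, 1:m] & pad[1:n, 2:(m + 1)] & pad[1:n, 3:(m + 2)] &
            pad[2:(n + 1), 1:m] & pad[2:(n + 1), 2:(m + 1)] &
            pad[2:(n + 1), 3:(m + 2)] &
            pad[3:(n + 2), 1:m] & pad[3:(n + 2), 2:(m + 1)] &
            pad[3:(n + 2), 3:(m + 2)]
  }
  mask
}

# connected component containing the largest blob of a logical mask;
# 8-connected breadth-first labeling (masks here are a few hundred pixels).
largest_blob <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0) return(NULL)
  n <- nrow(mask); m <- ncol(mask)
  lab <- matrix(0L, n, m)
  cur <- 0L
  sizes <- integer(0)
  for (s in seq_len(nrow(w))) {
    r0 <- w[s, 1]; c0 <- w[s, 2]
    if (lab[r0, c0] != 0L) next
    cur <- cur + 1L
    queue <- matrix(c(r0, c0), 1)
    lab[r0, c0] <- cur
    count <- 1L
    while (nrow(queue) > 0) {
      r <- queue[1, 1]; c <- queue[1, 2]
      queue <- queue[-1, , drop = FALSE]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= n && cc >= 1 && cc <= m &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- cur
          count <- count + 1L
          queue <- rbind(queue, c(rr, cc))
        }
      }
    }
    sizes[cur] <- count
  }
  lab == which.max(sizes)
}

#' Detect the ball-bearing centroid in a frame
#'
#' The BB appears as a dark disk inside the bright open field. The field
#' mask is taken at 50% of the image maximum; within it, pixels darker than
#' the midpoint between the field median and the darkest field pixel are
#' segmented, the largest 8-connected blob is kept, and the sub-pixel
#' centroid is computed with attenuation weights (field median minus
#' intensity).
#'
#' @param image a [preprocess()] result, an [epid_frame()], or a bare
#'   matrix.
#' @param native if `TRUE`, report native-resolution pixel coordinates even
#'   when the input raster is binned (`scale` inferred from raster size
#'   against `geom$panel_matrix`).
#' @param geom a [linac_geometry()].
#' @return `c(column = , row = )`, zero-based; native pixels if
#'   `native = TRUE`, else raster pixels. Raises an error when no blob is
#'   found.
#' @export
detect_bb_centroid <- function(image, native = TRUE,
                               geom = linac_geometry()) {
  px <- if (is.matrix(image)) image else image$pixels
  mx <- max(px)
  if (mx <= 0) stop("BB not found: empty image")
  field <- px > 0.5 * mx
  # shave the field border: binning and filtering leave partial-intensity
  # pixels along the aperture edge that would masquerade as a dark blob
  field <- erode_mask(field, 3L)
  if (!any(field)) stop("BB not found: no field region")
  med <- stats::median(px[field])
  lo <- min(px[field])
  if (med - lo < 0.05 * med) stop("BB not found: no attenuated blob in field")
  thr <- (med + lo) / 2
  mask <- field & px < thr
  blob <- largest_blob(mask)
  if (is.null(blob) || sum(blob) < 2) stop("BB not found: no blob")
  w <- which(blob, arr.ind = TRUE)
  wt <- med - px[blob]
  wt[wt < 0] <- 0
  if (sum(wt) <= 0) wt <- rep(1, nrow(w))
  col0 <- sum((w[, 2] - 1) * wt) / sum(wt)
  row0 <- sum((w[, 1] - 1) * wt) / sum(wt)
  if (native) {
    scale <- geom$panel_matrix / nrow(px)
    c(column = scale * col0 + (scale - 1) / 2,
      row = scale * row0 + (scale - 1) / 2)
  } else c(column = col0, row = row0)
}

#' Calibration run container
#'
#' @param direction `"CW"` or `"CC"`.
#' @param theta_deg gantry angles of the samples.
#' @param column,row detected BB centroid per sample, native pixels.
#' @return An object of class `calibration_run` (a data frame plus
#'   direction attribute).
#' @export
calibration_run <- function(direction, theta_deg, column, row) {
  stopifnot(direction %in% c("CW", "CC"))
  df <- data.frame(theta_deg = wrap_angle(theta_deg),
                   column = column, row = row)
  attr(df, "direction") <- direction
  class(df) <- c("calibration_run", "data.frame")
  df
}

#' Build the panel-position correction table from calibration runs
#'
#' Averages the detected BB centroids of all runs (both rotation
#' directions jointly, by default) on a regular 1-degree grid with
#' wrap-aware interpolation, and stores the per-angle offsets
#' `(511.5, 511.5) - mean centroid` that re-center the beam axis.
#'
#' @param runs list of [calibration_run()] data frames.
#' @param geom a [linac_geometry()].
#' @param grid_step_deg table angle grid step, degrees.
#' @param per_direction if `TRUE`, return a list of one table per rotation
#'   direction instead of the jointly averaged table.
#' @return A [panel_correction_table()] (or a named list of them).
#' @export
build_correction_table <- function(runs, geom = linac_geometry(),
                                   grid_step_deg = 1, per_direction = FALSE) {
  stopifnot(length(runs) >= 1)
  ctr <- (geom$panel_matrix - 1) / 2
  grid <- seq(0, 360 - grid_step_deg, by = grid_step_deg)
  one <- function(run_list) {
    acc_c <- matrix(NA_real_, length(run_list), length(grid))
    acc_r <- matrix(NA_real_, length(run_list), length(grid))
    for (i in seq_along(run_list)) {
      run <- run_list[[i]]
      o <- order(run$theta_deg)
      a <- run$theta_deg[o]
      gaps <- diff(c(a, a[1] + 360))
      if (any(gaps > 5)) {
        at <- a[which(gaps > 5)]
        stop("calibration run has angle gaps > 5 deg after: ",
             paste(sprintf("%.1f", at), collapse = ", "))
      }
      acc_c[i, ] <- interp_circular(a, run$column[o], grid)
      acc_r[i, ] <- interp_circular(a, run$row[o], grid)
    }
    panel_correction_table(grid, ctr - colMeans(acc_c), ctr - colMeans(acc_r))
  }
  if (!per_direction) return(one(runs))
  dirs <- vapply(runs, attr, character(1), "direction")
  lapply(split(runs, dirs), one)
}
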