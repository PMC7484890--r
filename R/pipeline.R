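# Cine-MV frame preprocessing: dark subtraction, flood-field gain
# correction, panel-position translation, 3x3 median filtering, 2x2 binning,
# thresholded histogram equalization and contour overlay rendering.

#' Construct an EPID frame
#'
#' @param pixels `panel x panel` numeric matrix of 16-bit intensities
#'   (rows = GT, columns = AB, zero-based coordinates in the API).
#' @param ts frame timestamp (completion of panel readout), seconds.
#' @return An object of class `epid_frame`.
#' @export
epid_frame <- function(pixels, ts) {
  stopifnot(is.matrix(pixels), nrow(pixels) == ncol(pixels))
  if (min(pixels) < 0 || max(pixels) > 65535)
    stop("intensities must lie in [0, 65535]")
  out <- list(pixels = pixels, ts = ts)
  class(out) <- "epid_frame"
  out
}

#' Gain calibration bundle
#'
#' @param dark dark (offset) frame, same raster as the frames.
#' @param floods list of `list(dose_rate, pixels)` flood-field frames for
#'   one nominal energy.
#' @param energy nominal energy, MV.
#' @return An object of class `gain_calibration`.
#' @export
gain_calibration <- function(dark, floods, energy = 6) {
  stopifnot(is.matrix(dark), length(floods) >= 1)
  for (f in floods) {
    stopifnot(!is.null(f$dose_rate), is.matrix(f$pixels))
    if (!all(dim(f$pixels) == dim(dark)))
      stop("flood/dark raster mismatch")
  }
  out <- list(dark = dark, floods = floods, energy = energy)
  class(out) <- "gain_calibration"
  out
}

#' Panel-position correction table
#'
#' Gantry-angle-indexed translation offsets (native pixels, AB then GT) that
#' bring the beam central axis back to the image center. Offsets are
#' interpolated wrap-aware at application time.
#'
#' @param angle_deg angles of the table grid, `[0, 360)`.
#' @param dx_ab,dy_gt offsets in native pixels.
#' @return An object of class `panel_correction_table` (a data frame).
#' @export
panel_correction_table <- function(angle_deg, dx_ab, dy_gt) {
  stopifnot(length(angle_deg) == length(dx_ab),
            length(angle_deg) == length(dy_gt))
  if (any(abs(c(dx_ab, dy_gt)) >= 16))
    stop("implausible panel offset (|offset| >= 16 px)")
  o <- order(wrap_angle(angle_deg))
  out <- data.frame(angle_deg = wrap_angle(angle_deg)[o],
                    dx_ab = dx_ab[o], dy_gt = dy_gt[o])
  class(out) <- c("panel_correction_table", "data.frame")
  out
}

#' Read / write a panel correction table as CSV
#'
#' Columns `angle_deg, dx_px, dy_px`.
#' @param table a [panel_correction_table()].
#' @param path file path.
#' @return `read_correction_table` returns a `panel_correction_table`.
#' @export
write_correction_table <- function(table, path) {
  df <- data.frame(angle_deg = table$angle_deg, dx_px = table$dx_ab,
                   dy_px = table$dy_gt)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_correction_table
#' @export
read_correction_table <- function(path) {
  df <- utils::read.csv(path)
  panel_correction_table(df$angle_deg, df$dx_px, df$dy_px)
}

# wrap-aware linear interpolation of a periodic table
interp_circular <- function(angle_grid, values, theta) {
  n <- length(angle_grid)
  if (n == 1) return(rep(values, length(theta)))
  a <- c(angle_grid[n] - 360, angle_grid, angle_grid[1] + 360)
  v <- c(values[n], values, values[1])
  stats::approx(a, v, xout = wrap_angle(theta))$y
}

#' Interpolate panel offsets at a gantry angle
#'
#' @param table a [panel_correction_table()].
#' @param theta_deg gantry angle, degrees.
#' @return `c(dx_ab = , dy_gt = )` in native pixels.
#' @export
correction_at <- function(table, theta_deg) {
  c(dx_ab = interp_circular(table$angle_deg, table$dx_ab, theta_deg),
    dy_gt = interp_circular(table$angle_deg, table$dy_gt, theta_deg))
}

# integer-pixel translation, zero fill
translate_image <- function(img, dx, dy) {
  dx <- round(dx); dy <- round(dy)
  if (dx == 0 && dy == 0) return(img)
  n <- nrow(img); m <- ncol(img)
  out <- matrix(0, n, m)
  src_r <- max(1, 1 - dy):min(n, n - dy)
  src_c <- max(1, 1 - dx):min(m, m - dx)
  if (length(src_r) > 0 && length(src_c) > 0)
    out[src_r + dy, src_c + dx] <- img[src_r, src_c]
  out
}

#' 3x3 median filter (edge-replicated borders)
#'
#' Vectorized exact 3x3 median via a 19-operation min/max sorting network
#' applied to whole shifted copies of the image.
#'
#' @param img numeric matrix.
#' @return Filtered matrix of the same size.
#' @export
median3x3 <- function(img) {
  n <- nrow(img); m <- ncol(img)
  if (n < 2 || m < 2) return(img)
  # edge-replicated pad
  pad <- matrix(0, n + 2, m + 2)
  pad[2:(n + 1), 2:(m + 1)] <- img
  pad[1, ] <- pad[2, ]; pad[n + 2, ] <- pad[n + 1, ]
  pad[, 1] <- pad[, 2]; pad[, m + 2] <- pad[, m + 1]
  p <- list()
  idx <- 1
  for (dr in 0:2) for (dc in 0:2) {
    p[[idx]] <- pad[(1 + dr):(n + dr), (1 + dc):(m + dc)]
    idx <- idx + 1
  }
  sw <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo; p[[j]] <<- hi
  }
  sw(2, 3); sw(5, 6); sw(8, 9); sw(1, 2); sw(4, 5); sw(7, 8)
  sw(2, 3); sw(5, 6); sw(8, 9); sw(1, 4); sw(6, 9); sw(5, 8)
  sw(4, 7); sw(2, 5); sw(3, 6); sw(5, 8); sw(5, 3); sw(7, 5); sw(5, 3)
  p[[5]]
}

#' 2x2 average binning
#'
#' Each output pixel is the mean of its 2x2 input block, halving the raster
#' to the working resolution of the projection maps.
#'
#' @param img numeric matrix with even dimensions.
#' @return Matrix of half the size.
#' @export
bin2x2 <- function(img) {
  n <- nrow(img); m <- ncol(img)
  if (n %% 2 != 0 || m %% 2 != 0) stop("image dimensions must be even")
  (img[seq(1, n, 2), seq(1, m, 2)] + img[seq(2, n, 2), seq(1, m, 2)] +
   img[seq(1, n, 2), seq(2, m, 2)] + img[seq(2, n, 2), seq(2, m, 2)]) / 4
}

#' Preprocess a raw EPID frame
#'
#' Applies, in order: dark-frame subtraction, flood-field gain correction
#' (flood at the nearest dose rate; correction `(raw - dark)/(flood - dark)`
#' rescaled to preserve the mean intensity), panel-position translation at
#' the current gantry angle (integer native pixels, so the beam axis sits at
#' the image center), 3x3 median filtering, and 2x2 binning. Nonpositive
#' gain denominators are replaced by the local 3x3 median of the gain map.
#'
#' @param frame an [epid_frame()].
#' @param cal a [gain_calibration()].
#' @param table a [panel_correction_table()] (or `NULL` to skip
#'   translation).
#' @param theta_deg gantry angle of the frame (for the table lookup).
#' @param dose_rate dose rate of the frame (flood selection).
#' @param geom a [linac_geometry()].
#' @return An object of class `processed_image`: `pixels` (binned matrix),
#'   `ts`, `theta_deg`.
#' @export
preprocess <- function(frame, cal, table = NULL, theta_deg = 0,
                       dose_rate = NULL, geom = linac_geometry()) {
  raw <- frame$pixels
  img <- pmax(raw - cal$dark, 0)
  rates <- vapply(cal$floods, `[[`, numeric(1), "dose_rate")
  pick <- if (is.null(dose_rate)) 1L else which.min(abs(rates - dose_rate))
  gain <- cal$floods[[pick]]$pixels - cal$dark
  if (any(gain <= 0)) {
    gm <- median3x3(gain)
    bad <- gain <= 0
    gain[bad] <- gm[bad]
    gain[gain <= 0] <- mean(gain[gain > 0])
  }
  img <- img / gain * mean(gain)
  if (!is.null(table)) {
    off <- correction_at(table, theta_deg)
    img <- translate_image(img, off[1], off[2])
  }
  img <- median3x3(img)
  img <- bin2x2(img)
  out <- list(pixels = img, ts = frame$ts, theta_deg = theta_deg)
  class(out) <- "processed_image"
  out
}

#' Thresholded histogram equalization to an 8-bit display image
#'
#' Pixels below `threshold_fraction` of the image maximum are set to 0; the
#' retained pixels are remapped through their empirical CDF onto 0..255:
#' `out = round(255 * (cdf(v) - cdf_min) / (1 - cdf_min))`, which is
#' monotone nondecreasing and pins the brightest level to 255. A constant
#' retained region maps entirely to 255; an all-zero image stays zero.
#'
#' @param image a [preprocess()] result or a bare matrix.
#' @param threshold_fraction fraction of the maximum gray level below which
#'   pixels are zeroed (default 0.70).
#' @return Integer matrix with values in 0..255.
#' @export
histogram_equalize <- function(image, threshold_fraction = 0.70) {
  stopifnot(threshold_fraction > 0, threshold_fraction < 1)
  px <- if (is.matrix(image)) image else image$pixels
  mx <- max(px)
  out <- matrix(0L, nrow(px), ncol(px))
  if (mx <= 0) return(out)
  thr <- threshold_fraction * mx
  keep <- px >= thr
  v <- px[keep]
  lev <- sort(unique(v))
  if (length(lev) == 1) {
    out[keep] <- 255L
    return(out)
  }
  counts <- tabulate(match(v, lev), nbins = length(lev))
  cdf <- cumsum(counts) / length(v)
  cdf_min <- cdf[1]
  mapped <- as.integer(round(255 * (cdf - cdf_min) / (1 - cdf_min)))
  out[keep] <- mapped[match(v, lev)]
  out
}

#' Render contour overlays on a display image
#'
#' Paints the boundary pixels of each visible overlay in its ROI color on
#' top of the 8-bit grayscale display image; everything else keeps the
#' grayscale value.
#'
#' @param display integer matrix from [histogram_equalize()] (binned
#'   resolution).
#' @param overlays list of [extract_contour()] results at the same
#'   resolution.
#' @param visibility logical vector (recycled) selecting which overlays to
#'   draw.
#' @return An `nrow x ncol x 3` numeric array with values in `[0, 1]`
#'   (RGB), suitable for [png::writePNG()].
#' @export
render_overlay <- function(display, overlays = list(), visibility = TRUE) {
  n <- nrow(display); m <- ncol(display)
  g <- display / 255
  img <- array(g, dim = c(n, m, 3))
  visibility <- rep_len(visibility, length(overlays))
  for (i in seq_along(overlays)) {
    if (!visibility[i]) next
    ov <- overlays[[i]]
    if (nrow(ov$boundary) == 0) next
    if (max(ov$boundary[, "row"]) >= n || max(ov$boundary[, "column"]) >= m)
      stop("overlay resolution does not match the display image")
    rr <- ov$boundary[, "row"] + 1; cc <- ov$boundary[, "column"] + 1
    col <- (ov$color %||% c(255, 255, 0)) / 255
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[cbind(rr, cc)] <- col[ch]
      img[, , ch] <- plane
    }
  }
  img
}

#' Write / read a raw frame raster
#'
#' Flat little-endian unsigned 16-bit binary, row-major (column index
#' fastest), `panel x panel` pixels, with a JSON-lines sidecar of
#' timestamps maintained by the caller.
#'
#' @param frame an [epid_frame()]; `path` file path.
#' @param path file path.
#' @param n panel size (pixels per side) for reading.
#' @param ts timestamp to attach on read.
#' @return `read_frame_raw` returns an `epid_frame`.
#' @export
write_frame_raw <- function(frame, path) {
  px <- t(frame$pixels)          # row-major on disk
  con <- file(path, "wb")
  on.exit(close(con))
  v <- as.integer(round(px))
  v[v > 32767] <- v[v > 32767] - 65536L   # two's complement for writeBin
  writeBin(v, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_frame_raw
#' @export
read_frame_raw <- function(path, n = 1024L, ts = NA_real_) {
  v <- readBin(path, "integer", n = n * n, size = 2, endian = "little",
               signed = FALSE)
  epid_frame(t(matrix(as.numeric(v), nrow = n)), ts)
}
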