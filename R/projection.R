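# Beam's-eye-view ROI projection: voxelization of planar contours on the
# planning-CT lattice, first-hit ray casting onto the virtual EPID at 2x2
# detector-group resolution, 8-neighbor boundary extraction, and the
# precomputed 0.5-degree projection set used at treatment time.

# round half away from zero (fractional voxel indices are always positive
# here, but keep the rule explicit for determinism)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Even-odd point-in-polygon, boundary-inclusive: points within `eps` of an
# edge (including vertices) count as inside.
point_in_polygon <- function(px, py, poly, eps = 1e-9) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- poly[j, 1]; y1 <- poly[j, 2]; x2 <- poly[i, 1]; y2 <- poly[i, 2]
    crosses <- (y1 > py) != (y2 > py)
    if (any(crosses)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & (px < xint))
    }
    # distance to segment
    dx <- x2 - x1; dy <- y2 - y1
    L2 <- dx * dx + dy * dy
    t <- if (L2 > 0) pmin(pmax(((px - x1) * dx + (py - y1) * dy) / L2, 0), 1)
         else 0
    d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
    on_edge <- on_edge | d2 <= eps^2
    j <- i
  }
  inside | on_edge
}

#' Voxelize a planar-contoured ROI on the CT lattice
#'
#' Builds a binary occupancy grid with the planning-CT geometry: a voxel is
#' occupied when its center lies inside the ROI polygon of its slice
#' (even-odd rule; points on the polygon boundary count as inside). Multiple
#' polygons on one slice combine by even-odd parity, so nested contours form
#' holes.
#'
#' @param roi one ROI of a [read_structure_set()] result (a list with a
#'   `contours` field), or a bare list of Nx3 contour matrices.
#' @param ct a [read_ct_geometry()] result.
#' @return An object of class `voxel_grid`: `ct` and `occ`, a
#'   `rows x cols x slices` logical array.
#' @export
voxelize_roi <- function(roi, ct) {
  contours <- if (!is.null(roi$contours)) roi$contours else roi
  occ <- array(FALSE, dim = ct$dims)
  xs <- ct$origin[1] + (seq_len(ct$dims[2]) - 1) * ct$spacing[2]
  ys <- ct$origin[2] + (seq_len(ct$dims[1]) - 1) * ct$spacing[1]
  for (pts in contours) {
    if (nrow(pts) < 3) stop("contour with fewer than 3 vertices")
    z <- pts[1, 3]
    k <- ct_nearest_slice(ct, z)
    if (k < 1 || k > ct$dims[3]) stop("contour outside the CT grid (z=", z, ")")
    jr <- range(which(xs >= min(pts[, 1]) - ct$spacing[2] &
                      xs <= max(pts[, 1]) + ct$spacing[2]))
    ir <- range(which(ys >= min(pts[, 2]) - ct$spacing[1] &
                      ys <= max(pts[, 2]) + ct$spacing[1]))
    if (any(!is.finite(jr)) || any(!is.finite(ir))) next
    jj <- jr[1]:jr[2]; ii <- ir[1]:ir[2]
    g <- expand.grid(i = ii, j = jj)
    inside <- point_in_polygon(xs[g$j], ys[g$i], pts[, 1:2, drop = FALSE])
    idx <- cbind(g$i, g$j, k)[inside, , drop = FALSE]
    occ[idx] <- xor(occ[idx], TRUE)
  }
  out <- list(ct = ct, occ = occ)
  class(out) <- "voxel_grid"
  out
}

#' Isotropic morphological dilation of a voxel grid
#'
#' Dilates the occupied set with a spherical structuring element of physical
#' radius `radius_mm`, honoring anisotropic voxel spacing: an output voxel is
#' occupied iff some input voxel center lies within `radius_mm` of its
#' center. Used to grow fiducial ROIs into tolerance margins.
#'
#' @param grid a [voxelize_roi()] result.
#' @param radius_mm expansion radius, mm (>= 0).
#' @return A `voxel_grid`.
#' @export
dilate_isotropic <- function(grid, radius_mm) {
  stopifnot(radius_mm >= 0)
  if (radius_mm == 0 || !any(grid$occ)) return(grid)
  sp <- grid$ct$spacing            # (row, col, slice)
  di <- floor(radius_mm / sp[1]); dj <- floor(radius_mm / sp[2])
  dk <- floor(radius_mm / sp[3])
  occ <- grid$occ
  out <- occ
  d <- dim(occ)
  for (a in -di:di) for (b in -dj:dj) for (c in -dk:dk) {
    if (a == 0 && b == 0 && c == 0) next
    if ((a * sp[1])^2 + (b * sp[2])^2 + (c * sp[3])^2 > radius_mm^2 + 1e-9) next
    si <- max(1, 1 - a):min(d[1], d[1] - a)
    sj <- max(1, 1 - b):min(d[2], d[2] - b)
    sk <- max(1, 1 - c):min(d[3], d[3] - c)
    out[si + a, sj + b, sk + c] <- out[si + a, sj + b, sk + c] |
      occ[si, sj, sk]
  }
  grid$occ <- out
  grid
}

# Room-frame coordinate vectors (cm) of the voxel-center planes of a grid.
grid_room_axes <- function(ct, isocenter_mm) {
  list(
    # X (lateral) varies with column index j
    x = (ct$origin[1] + (seq_len(ct$dims[2]) - 1) * ct$spacing[2] -
           isocenter_mm[1]) / 10,
    # Z (vertical) varies with row index i: Z = -(py - iy)/10
    z = -(ct$origin[2] + (seq_len(ct$dims[1]) - 1) * ct$spacing[1] -
            isocenter_mm[2]) / 10,
    # Y (longitudinal) varies with slice index k
    y = (ct$origin[3] + (seq_len(ct$dims[3]) - 1) * ct$spacing[3] -
           isocenter_mm[3]) / 10
  )
}

#' Ray-cast a voxelized ROI onto the virtual EPID
#'
#' For each 2x2 detector group (one binned pixel), the straight line from
#' the radiation source through the pixel is intersected with every lattice
#' plane that holds at least one occupied voxel; each intersection point is
#' converted to a fractional voxel index, rounded to the nearest integer
#' (half away from zero), and tested against the occupancy grid. The pixel
#' is set as soon as one intersection lands in an occupied voxel
#' (first-hit early exit); only intersections on the source-to-panel
#' segment count. Planes are visited in order of increasing distance from
#' the source, which makes the early exit a true first hit; the binary
#' result does not depend on the ordering.
#'
#' @param grid a [voxelize_roi()] result.
#' @param theta_deg gantry angle, degrees.
#' @param isocenter_mm plan isocenter in patient coordinates, mm.
#' @param geom a [linac_geometry()].
#' @return An object of class `binary_projection_map`: `pixels` (a
#'   `512 x 512` logical matrix, rows = GT, columns = AB), `theta_deg`,
#'   `roi_name` (filled by [precompute_set()]).
#' @export
raycast_projection <- function(grid, theta_deg, isocenter_mm,
                               geom = linac_geometry()) {
  nb <- geom$panel_matrix / 2
  map <- matrix(FALSE, nb, nb)
  occ <- grid$occ
  if (!any(occ)) {
    out <- list(pixels = map, theta_deg = wrap_angle(theta_deg),
                roi_name = NA_character_)
    class(out) <- "binary_projection_map"
    return(out)
  }
  th <- wrap_angle(theta_deg) * pi / 180
  sad <- geom$sad_cm
  s <- c(sad * sin(th), 0, sad * cos(th))
  ax <- grid_room_axes(grid$ct, isocenter_mm)
  w <- which(occ, arr.ind = TRUE)
  ir <- range(w[, 1]); jr <- range(w[, 2]); kr <- range(w[, 3])
  has_i <- sort(unique(w[, 1])); has_j <- sort(unique(w[, 2]))
  has_k <- sort(unique(w[, 3]))

  # candidate pixel window: project the corners of the occupied bounding box
  corners <- as.matrix(expand.grid(x = ax$x[jr], y = ax$y[kr], z = ax$z[ir]))
  uhat <- c(cos(th), 0, -sin(th))
  uv <- t(apply(corners, 1, function(o) {
    t0 <- sad^2 / (sad^2 - sum(s * o))
    p <- s + t0 * (o - s)
    c(sum(p * uhat), p[2])
  }))
  pitch_cm <- 2 * geom$pixel_iso_mm / 10
  ctr <- (nb - 1) / 2
  cb <- ctr + uv[, 1] / pitch_cm     # 0-based binned column
  rb <- ctr + uv[, 2] / pitch_cm
  margin <- 3
  c0 <- max(0, floor(min(cb)) - margin); c1 <- min(nb - 1, ceiling(max(cb)) + margin)
  r0 <- max(0, floor(min(rb)) - margin); r1 <- min(nb - 1, ceiling(max(rb)) + margin)
  if (c0 > c1 || r0 > r1) {
    out <- list(pixels = map, theta_deg = wrap_angle(theta_deg),
                roi_name = NA_character_)
    class(out) <- "binary_projection_map"
    return(out)
  }
  cand <- expand.grid(col = c0:c1, row = r0:r1)
  u <- (cand$col - ctr) * pitch_cm
  v <- (cand$row - ctr) * pitch_cm
  # ray direction to the isocenter-plane point of each pixel
  p_iso <- cbind(u * uhat[1], v, u * uhat[3])
  dxr <- p_iso[, 1] - s[1]; dyr <- p_iso[, 2] - s[2]; dzr <- p_iso[, 3] - s[3]
  hit <- rep(FALSE, nrow(cand))
  t_max <- geom$mag                       # panel plane parameter

  sp <- grid$ct$spacing
  dims <- grid$ct$dims
  # plane list: (axis, index, room coordinate, distance from source)
  planes <- rbind(
    if (length(has_j)) cbind(1, has_j, ax$x[has_j]),
    if (length(has_k)) cbind(2, has_k, ax$y[has_k]),
    if (length(has_i)) cbind(3, has_i, ax$z[has_i]))
  sdist <- abs(planes[, 3] - c(s[1], s[2], s[3])[planes[, 1]])
  planes <- planes[order(sdist), , drop = FALSE]

  for (pi in seq_len(nrow(planes))) {
    if (all(hit)) break
    axis <- planes[pi, 1]; coord <- planes[pi, 3]
    act <- which(!hit)
    dcomp <- switch(axis, dxr, dyr, dzr)[act]
    scomp <- s[c(1, 2, 3)[axis]]
    ok <- abs(dcomp) > 1e-12
    tt <- (coord - scomp) / dcomp
    ok <- ok & tt >= 0 & tt <= t_max
    if (!any(ok)) next
    act <- act[ok]; tt <- tt[ok]
    xi <- s[1] + tt * dxr[act]
    yi <- s[2] + tt * dyr[act]
    zi <- s[3] + tt * dzr[act]
    # room -> fractional 1-based voxel indices
    fj <- (xi * 10 + isocenter_mm[1] - grid$ct$origin[1]) / sp[2] + 1
    fi <- (-zi * 10 + isocenter_mm[2] - grid$ct$origin[2]) / sp[1] + 1
    fk <- (yi * 10 + isocenter_mm[3] - grid$ct$origin[3]) / sp[3] + 1
    vi <- round_half_away(fi); vj <- round_half_away(fj); vk <- round_half_away(fk)
    inb <- vi >= 1 & vi <= dims[1] & vj >= 1 & vj <= dims[2] &
           vk >= 1 & vk <= dims[3]
    if (!any(inb)) next
    sel <- act[inb]
    occ_hit <- occ[cbind(vi[inb], vj[inb], vk[inb])]
    hit[sel[occ_hit]] <- TRUE
  }
  map[cbind(cand$row + 1L, cand$col + 1L)] <- hit
  out <- list(pixels = map, theta_deg = wrap_angle(theta_deg),
              roi_name = NA_character_)
  class(out) <- "binary_projection_map"
  out
}

#' Extract the boundary contour and centroid of a binary projection map
#'
#' A map pixel belongs to the contour iff its value is 1 and at least one of
#' its eight neighbors is 0, or it lies on the boundary of the map. The
#' centroid is the area centroid of the full filled projection (mean of all
#' value-1 pixel coordinates), not of the boundary pixels.
#'
#' @param map a [raycast_projection()] result (or a bare logical matrix).
#' @param color RGB triplet for display.
#' @return An object of class `contour_overlay`: `boundary` (Nx2 matrix of
#'   zero-based `(column, row)` pixels), `centroid` (`c(column, row)` or
#'   `NULL` when the map is empty, with `empty = TRUE`), `color`,
#'   `theta_deg`, `roi_name`.
#' @export
extract_contour <- function(map, color = c(255, 255, 0)) {
  px <- if (is.matrix(map)) map else map$pixels
  theta <- if (is.matrix(map)) NA_real_ else map$theta_deg
  roi <- if (is.matrix(map)) NA_character_ else map$roi_name
  n <- nrow(px); m <- ncol(px)
  if (!any(px)) {
    out <- list(boundary = matrix(numeric(0), 0, 2,
                                  dimnames = list(NULL, c("column", "row"))),
                centroid = NULL, empty = TRUE, color = color,
                theta_deg = theta, roi_name = roi)
    class(out) <- "contour_overlay"
    return(out)
  }
  pad <- matrix(FALSE, n + 2, m + 2)
  pad[2:(n + 1), 2:(m + 1)] <- px
  all8 <- pad[1:n, 1:m] & pad[1:n, 2:(m + 1)] & pad[1:n, 3:(m + 2)] &
          pad[2:(n + 1), 1:m] & pad[2:(n + 1), 3:(m + 2)] &
          pad[3:(n + 2), 1:m] & pad[3:(n + 2), 2:(m + 1)] & pad[3:(n + 2), 3:(m + 2)]
  boundary <- px & !all8
  w <- which(boundary, arr.ind = TRUE)
  b <- cbind(column = w[, 2] - 1, row = w[, 1] - 1)
  wf <- which(px, arr.ind = TRUE)
  centroid <- c(column = mean(wf[, 2] - 1), row = mean(wf[, 1] - 1))
  out <- list(boundary = b[order(b[, 1], b[, 2]), , drop = FALSE],
              centroid = centroid, empty = FALSE, color = color,
              theta_deg = theta, roi_name = roi)
  class(out) <- "contour_overlay"
  out
}

#' Precompute the projection set for selected ROIs
#'
#' Runs voxelization once per ROI and ray casting + contour extraction at
#' every gantry angle of the grid (0, step, ..., 360 - step; 720 entries at
#' the default 0.5 degree step). This is the offline step performed before
#' the first treatment fraction.
#'
#' @param rois a [read_structure_set()] result.
#' @param plan a [read_plan()] result (supplies the isocenter).
#' @param ct a [read_ct_geometry()] result.
#' @param geom a [linac_geometry()].
#' @param roi_names ROIs to project (default: all in `rois`).
#' @param dilate_mm optional isotropic expansion applied before projection
#'   (tolerance margin), mm.
#' @return An object of class `projection_set`: `angle_step_deg`, `angles`,
#'   `rois` (named list, each with `color` and `overlays`, one
#'   [extract_contour()] result per grid angle), `provenance`.
#' @export
precompute_set <- function(rois, plan, ct, geom = linac_geometry(),
                           roi_names = NULL, dilate_mm = 0) {
  if (is.null(roi_names)) roi_names <- names(rois)
  if (length(roi_names) == 0) stop("no ROIs selected")
  angles <- seq(0, 360 - geom$angle_step_deg, by = geom$angle_step_deg)
  out_rois <- list()
  for (nm in roi_names) {
    roi <- rois[[nm]]
    if (is.null(roi)) stop("unknown ROI '", nm, "'")
    grid <- tryCatch(voxelize_roi(roi, ct),
                     error = function(e) stop("ROI '", nm, "': ",
                                              conditionMessage(e)))
    if (dilate_mm > 0) grid <- dilate_isotropic(grid, dilate_mm)
    overlays <- vector("list", length(angles))
    for (i in seq_along(angles)) {
      m <- raycast_projection(grid, angles[i], plan$isocenter, geom)
      ov <- extract_contour(m, roi$color)
      ov$theta_deg <- angles[i]; ov$roi_name <- nm
      overlays[[i]] <- ov
    }
    out_rois[[nm]] <- list(color = roi$color, overlays = overlays)
  }
  set <- list(angle_step_deg = geom$angle_step_deg, angles = angles,
              rois = out_rois,
              provenance = list(n_angles = length(angles),
                                roi_names = roi_names))
  class(set) <- "projection_set"
  set
}

#' Look up the precomputed overlay nearest to a gantry angle
#'
#' Nearest-grid-angle lookup, wrap-aware across 0/360; exact midpoints
#' resolve toward the lower grid angle.
#'
#' @param set a [precompute_set()] result.
#' @param roi_name ROI name.
#' @param theta_deg gantry angle, degrees.
#' @return A `contour_overlay`.
#' @export
lookup_overlay <- function(set, roi_name, theta_deg) {
  r <- set$rois[[roi_name]]
  if (is.null(r)) stop("unknown ROI '", roi_name, "' in projection set")
  step <- set$angle_step_deg
  n <- length(set$angles)
  k <- ceiling(wrap_angle(theta_deg) / step - 0.5) %% n
  r$overlays[[k + 1]]
}

#' Save / load a projection set
#'
#' Versioned JSON container; numeric values are serialized at full precision
#' so that a save/load round trip reproduces the set exactly.
#'
#' @param set a [precompute_set()] result.
#' @param path file path (`.json`).
#' @return `load_projection_set` returns a `projection_set`.
#' @export
save_projection_set <- function(set, path) {
  ser <- list(
    container = "cinemv-projection-set", version = 1L,
    angle_step_deg = set$angle_step_deg,
    provenance = set$provenance,
    rois = lapply(set$rois, function(r) list(
      color = r$color,
      overlays = lapply(r$overlays, function(ov) list(
        theta_deg = ov$theta_deg,
        boundary = if (nrow(ov$boundary)) unname(ov$boundary) else NULL,
        # centroids as %.17g strings: doubles survive bit-exactly
        centroid = if (!is.null(ov$centroid))
          sprintf("%.17g", unname(ov$centroid)) else NULL))))
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_projection_set
#' @export
load_projection_set <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(ser$container, "cinemv-projection-set"))
    stop("not a projection-set container: ", path)
  step <- ser$angle_step_deg
  rois <- lapply(names(ser$rois), function(nm) {
    r <- ser$rois[[nm]]
    color <- unlist(r$color)
    overlays <- lapply(r$overlays, function(ov) {
      b <- if (is.null(ov$boundary)) {
        matrix(numeric(0), 0, 2, dimnames = list(NULL, c("column", "row")))
      } else {
        m <- do.call(rbind, lapply(ov$boundary, unlist))
        colnames(m) <- c("column", "row"); m
      }
      ctr <- if (is.null(ov$centroid)) NULL else {
        v <- as.numeric(unlist(ov$centroid)); names(v) <- c("column", "row"); v
      }
      out <- list(boundary = b, centroid = ctr, empty = is.null(ctr),
                  color = color, theta_deg = ov$theta_deg, roi_name = nm)
      class(out) <- "contour_overlay"
      out
    })
    list(color = color, overlays = overlays)
  })
  names(rois) <- names(ser$rois)
  angles <- seq(0, 360 - step, by = step)
  set <- list(angle_step_deg = step, angles = angles, rois = rois,
              provenance = ser$provenance)
  class(set) <- "projection_set"
  set
}

#' Verify that the primary field stays within the EPID for every control point
#'
#' For each control point of each beam, the open aperture (per-leaf-pair
#' rectangles clipped by the jaws, or the jaw rectangle when no MLC is
#' present) is rotated by the collimator angle and its vertices, grown by a
#' security margin, are tested against the square field of view of the
#' detector at isocenter scale. Treatments whose field can spill past the
#' imaging area must not be monitored this way (the panel would be at risk),
#' so any failing control point makes the beam ineligible.
#'
#' @param plan a [read_plan()] result.
#' @param geom a [linac_geometry()].
#' @param margin_mm security margin at isocenter scale, mm.
#' @return A data frame with one row per control point: `beam`,
#'   `control_point`, `max_extent_mm` (largest |coordinate| of any aperture
#'   vertex after collimator rotation), `pass`.
#' @export
field_within_epid <- function(plan, geom = linac_geometry(), margin_mm = 5) {
  half_fov <- 10 * geom$fov_iso_cm / 2
  rows <- list()
  for (b in plan$beams) {
    bounds <- b$leaf_boundaries
    for (cp in b$control_points) {
      verts <- aperture_vertices(cp, bounds)
      ext <- if (nrow(verts) == 0) 0 else {
        phi <- -b$collimator_deg * pi / 180
        rx <- verts[, 1] * cos(phi) - verts[, 2] * sin(phi)
        ry <- verts[, 1] * sin(phi) + verts[, 2] * cos(phi)
        max(abs(c(rx, ry)))
      }
      rows[[length(rows) + 1]] <- data.frame(
        beam = b$name, control_point = cp$index,
        max_extent_mm = ext, pass = ext + margin_mm <= half_fov)
    }
  }
  do.call(rbind, rows)
}

aperture_vertices <- function(cp, leaf_bounds) {
  jx <- cp$jaw_x; jy <- cp$jaw_y
  if (is.null(cp$mlc) || is.null(leaf_bounds)) {
    return(cbind(x = c(jx[1], jx[2], jx[2], jx[1]),
                 y = c(jy[1], jy[1], jy[2], jy[2])))
  }
  out <- list()
  n <- ncol(cp$mlc)
  for (p in seq_len(n)) {
    x1 <- max(cp$mlc[1, p], jx[1]); x2 <- min(cp$mlc[2, p], jx[2])
    y1 <- max(leaf_bounds[p], jy[1]); y2 <- min(leaf_bounds[p + 1], jy[2])
    if (x2 - x1 <= 1e-9 || y2 - y1 <= 1e-9) next
    out[[length(out) + 1]] <- cbind(x = c(x1, x2, x2, x1),
                                    y = c(y1, y1, y2, y2))
  }
  if (length(out) == 0) matrix(numeric(0), 0, 2) else do.call(rbind, out)
}
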