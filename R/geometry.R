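#' Linac and virtual-EPID geometry
#'
#' Bundles the constants of the imaging chain: source-to-axis distance (SAD),
#' source-to-detector distance (SDD), the native detector matrix, the field of
#' view at the isocenter plane, the frame integration time and the
#' gantry-angle step of the precomputed projection set. The per-pixel spacing
#' at isocenter scale follows from the field of view and the matrix
#' (`10 * fov_iso_cm / panel_matrix` mm), 0.25 mm for the defaults; after 2x2
#' binning the working resolution is 0.5 mm.
#'
#' The gantry-angle convention is IEC-style: at `theta = 0` the source sits
#' above the isocenter at `(0, SAD)` in the lateral-vertical (X-Z) plane, and
#' increasing `theta` moves the source toward +X, i.e. the source position is
#' `S(theta) = (SAD sin(theta), SAD cos(theta))`.
#'
#' @param sad_cm source-to-axis distance (cm).
#' @param sdd_cm source-to-detector distance (cm).
#' @param panel_matrix native detector pixels per side.
#' @param fov_iso_cm side length of the field of view at the isocenter plane
#'   (cm).
#' @param integration_time_s frame integration time (s).
#' @param angle_step_deg gantry-angle step of the precomputed projection set
#'   (degrees).
#' @return An object of class `linac_geometry`: a list with the arguments
#'   plus `pixel_iso_mm` (native per-pixel spacing at isocenter scale, mm)
#'   and `mag` (imaging magnification `sdd / sad`).
#' @export
#' @examples
#' g <- linac_geometry()
#' g$pixel_iso_mm  # 0.25 mm
linac_geometry <- function(sad_cm = 100, sdd_cm = 160, panel_matrix = 1024L,
                           fov_iso_cm = 25.6, integration_time_s = 0.433,
                           angle_step_deg = 0.5) {
  stopifnot(sad_cm > 0, sdd_cm > sad_cm, panel_matrix %% 2 == 0,
            fov_iso_cm > 0, integration_time_s > 0, angle_step_deg > 0)
  g <- list(
    sad_cm = sad_cm, sdd_cm = sdd_cm, panel_matrix = as.integer(panel_matrix),
    fov_iso_cm = fov_iso_cm, integration_time_s = integration_time_s,
    angle_step_deg = angle_step_deg,
    pixel_iso_mm = 10 * fov_iso_cm / panel_matrix,
    mag = sdd_cm / sad_cm
  )
  class(g) <- "linac_geometry"
  g
}

#' @export
print.linac_geometry <- function(x, ...) {
  cat(sprintf(
    paste0("<linac_geometry> SAD %.4g cm, SDD %.4g cm (mag %.3g), %dx%d panel,\n",
           "  FOV %.4g cm at iso (%.4g mm/px native, %.4g mm binned),\n",
           "  integration %.3f s, projection step %.2g deg\n"),
    x$sad_cm, x$sdd_cm, x$mag, x$panel_matrix, x$panel_matrix,
    x$fov_iso_cm, x$pixel_iso_mm, 2 * x$pixel_iso_mm,
    x$integration_time_s, x$angle_step_deg))
  invisible(x)
}

#' Load linac geometry from a YAML or JSON config file
#'
#' Unspecified fields fall back to the defaults of [linac_geometry()].
#'
#' @param path path to a YAML or JSON file whose keys match the arguments of
#'   [linac_geometry()].
#' @return A `linac_geometry` object.
#' @export
read_linac_geometry <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(linac_geometry))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown geometry fields: ", paste(bad, collapse = ", "))
  do.call(linac_geometry, cfg)
}

#' Reduce a gantry angle to [0, 360)
#'
#' Signed angles in (-180, 180] (or any real) are accepted at every public
#' entry point and reduced internally.
#'
#' @param theta_deg gantry angle(s), degrees, any real.
#' @return Angle(s) in `[0, 360)`.
#' @export
wrap_angle <- function(theta_deg) {
  stopifnot(all(is.finite(theta_deg)))
  theta_deg %% 360
}

#' Express a gantry angle in the signed (-180, 180] convention
#'
#' @inheritParams wrap_angle
#' @return Angle(s) in `(-180, 180]`.
#' @export
signed_angle <- function(theta_deg) {
  a <- wrap_angle(theta_deg)
  ifelse(a > 180, a - 360, a)
}

#' A point in the treatment-room frame
#'
#' Room coordinates: X lateral, Y longitudinal (gun-target), Z vertical, all
#' in cm, origin at the linac isocenter.
#'
#' @param x,y,z coordinates (cm).
#' @return A named numeric vector of class `room_point`.
#' @export
room_point <- function(x = 0, y = 0, z = 0) {
  stopifnot(is.finite(x), is.finite(y), is.finite(z))
  p <- c(x = x, y = y, z = z)
  class(p) <- "room_point"
  p
}

#' Radiation source position for a gantry angle
#'
#' The source rotates in the lateral-vertical (X-Z) plane on a circle of
#' radius SAD: `S(theta) = (SAD sin(theta), SAD cos(theta))`.
#'
#' @param theta_deg gantry angle(s), degrees.
#' @param geom a [linac_geometry()].
#' @return For scalar input, `c(x = , z = )` in cm; for vector input a
#'   2-column matrix.
#' @export
source_position <- function(theta_deg, geom = linac_geometry()) {
  th <- wrap_angle(theta_deg) * pi / 180
  out <- cbind(x = geom$sad_cm * sin(th), z = geom$sad_cm * cos(th))
  if (length(theta_deg) == 1L) out[1L, ] else out
}

#' Project a room point onto the isocenter plane
#'
#' Intersects the ray from the source through the point with the plane
#' through the isocenter perpendicular to the beam central axis. The signed
#' lateral coordinate `u` lies along the in-plane axis `u_hat =
#' (cos(theta), 0, -sin(theta))`, so that for an object on the +X half-line
#' the auxiliary angle `beta = atan(u / SAD)` is positive for gantry angles
#' in the closed interval [-90, 90] degrees (boundary included) and negative
#' otherwise. The longitudinal (GT) coordinate `v` is returned alongside.
#'
#' For a point `(Ox, 0, 0)` the closed form is
#' `u = SAD * Ox * cos(theta) / (SAD - Ox * sin(theta))`.
#'
#' @param point a [room_point()] (cm).
#' @param theta_deg gantry angle, degrees.
#' @param geom a [linac_geometry()].
#' @return A list of class `projection_result`: `u_cm`, `v_cm`, `beta_rad`,
#'   `scale` (the magnification factor from object plane to isocenter plane).
#' @export
project_point <- function(point, theta_deg, geom = linac_geometry()) {
  th <- wrap_angle(theta_deg) * pi / 180
  sad <- geom$sad_cm
  s <- c(sad * sin(th), 0, sad * cos(th))          # source
  o <- as.numeric(point)[1:3]
  d <- o - s
  if (sqrt(sum(d^2)) < 1e-9)
    stop("degenerate geometry: point coincides with the radiation source")
  # plane through origin with normal s/|s|; ray S + t (O - S)
  denom <- sum(s * s) - sum(s * o)                  # SAD^2 - S.O
  if (abs(denom) < 1e-12 * sad^2)
    stop("degenerate geometry: ray parallel to the isocenter plane")
  t <- sum(s * s) / denom
  p <- s + t * d
  u_hat <- c(cos(th), 0, -sin(th))
  u <- sum(p * u_hat)
  v <- p[2]
  res <- list(u_cm = u, v_cm = v, beta_rad = atan(u / sad), scale = t)
  class(res) <- "projection_result"
  res
}

#' Projection position error for a gantry-angle error
#'
#' The lateral (AB-direction) displacement, at isocenter scale, of the
#' projection of a fixed object when the gantry angle used for projection is
#' off by `epsilon_deg`: `P(theta + epsilon) - P(theta)`, reported in mm.
#'
#' @param point a [room_point()] (cm).
#' @param theta_deg nominal gantry angle, degrees.
#' @param epsilon_deg gantry-angle error, degrees.
#' @param geom a [linac_geometry()].
#' @return Signed error in mm at isocenter scale. Multiply by `geom$mag` for
#'   the physical displacement at the detector plane.
#' @export
projection_error <- function(point, theta_deg, epsilon_deg,
                             geom = linac_geometry()) {
  stopifnot(is.finite(epsilon_deg))
  u1 <- project_point(point, theta_deg + epsilon_deg, geom)$u_cm
  u0 <- project_point(point, theta_deg, geom)$u_cm
  (u1 - u0) * 10
}

#' Sweep the projection error over gantry angles
#'
#' @param point a [room_point()] (cm).
#' @param epsilon_deg gantry-angle error, degrees.
#' @param theta_grid_deg gantry angles to evaluate, degrees.
#' @param geom a [linac_geometry()].
#' @return A data frame with columns `theta_deg` and `error_mm`.
#' @export
error_sweep <- function(point, epsilon_deg,
                        theta_grid_deg = seq(0, 359.9, by = 0.1),
                        geom = linac_geometry()) {
  stopifnot(length(theta_grid_deg) > 0)
  err <- vapply(theta_grid_deg, function(th)
    projection_error(point, th, epsilon_deg, geom), numeric(1))
  data.frame(theta_deg = theta_grid_deg, error_mm = err)
}

#' Convert isocenter-plane mm to pixel coordinates
#'
#' Pixel coordinates are zero-based, column 0..panel_matrix-1, matching the
#' panel readout convention; the beam central axis maps to the image center
#' (511.5, 511.5) native or (255.5, 255.5) binned for the default panel.
#' Columns increase with +u (lateral, AB) and rows with +v (longitudinal,
#' GT).
#'
#' @param u_mm lateral (AB) coordinate at isocenter scale, mm.
#' @param v_mm longitudinal (GT) coordinate at isocenter scale, mm.
#' @param geom a [linac_geometry()].
#' @param binned if `TRUE`, return 2x2-binned coordinates (0.5 mm pitch).
#' @return `c(column = , row = )`, zero-based, possibly fractional.
#' @export
iso_mm_to_pixel <- function(u_mm, v_mm, geom = linac_geometry(),
                            binned = FALSE) {
  half_mm <- 10 * geom$fov_iso_cm / 2
  if (any(abs(u_mm) > half_mm) || any(abs(v_mm) > half_mm))
    stop("point falls outside the detector field of view")
  n <- if (binned) geom$panel_matrix / 2 else geom$panel_matrix
  pitch <- if (binned) 2 * geom$pixel_iso_mm else geom$pixel_iso_mm
  ctr <- (n - 1) / 2
  c(column = ctr + u_mm / pitch, row = ctr + v_mm / pitch)
}

#' Convert pixel coordinates to isocenter-plane mm
#'
#' Inverse of [iso_mm_to_pixel()].
#'
#' @param column,row zero-based pixel coordinates (possibly fractional).
#' @param geom a [linac_geometry()].
#' @param binned if `TRUE`, coordinates are at binned (512) resolution.
#' @return `c(u_mm = , v_mm = )` at isocenter scale.
#' @export
pixel_to_iso_mm <- function(column, row, geom = linac_geometry(),
                            binned = FALSE) {
  n <- if (binned) geom$panel_matrix / 2 else geom$panel_matrix
  pitch <- if (binned) 2 * geom$pixel_iso_mm else geom$pixel_iso_mm
  ctr <- (n - 1) / 2
  c(u_mm = (column - ctr) * pitch, v_mm = (row - ctr) * pitch)
}
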