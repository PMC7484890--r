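#' Read the planning-CT lattice geometry from a DICOM series
#'
#' Only axial series with identity orientation (direction cosines
#' `1,0,0,0,1,0`, head-first supine) are supported. Slices are sorted by
#' their position along the slice normal; file order does not matter.
#'
#' @param files character vector of DICOM CT file paths (one per slice).
#' @return An object of class `ct_geometry`: `origin` (patient mm of the
#'   first voxel center, lowest slice), `spacing` (`c(row, col, slice)` mm),
#'   `dims` (`c(rows, cols, slices)`), `orientation` (6 direction cosines),
#'   `frame_of_reference`.
#' @export
read_ct_geometry <- function(files) {
  if (length(files) < 2)
    stop("need at least two slices to establish the slice spacing")
  slices <- lapply(files, read_dicom_file)
  fors <- vapply(slices, function(s)
    dcm_get(s, "00200052", TRUE, "FrameOfReferenceUID"), character(1))
  if (length(unique(fors)) != 1)
    stop("CT series mixes frames of reference")
  ori <- dcm_get(slices[[1]], "00200037", TRUE, "ImageOrientationPatient")
  if (max(abs(ori - c(1, 0, 0, 0, 1, 0))) > 1e-6)
    stop("only identity (axial, head-first supine) orientation is supported")
  rows <- unique(vapply(slices, function(s) as.integer(
    dcm_get(s, "00280010", TRUE, "Rows")), integer(1)))
  cols <- unique(vapply(slices, function(s) as.integer(
    dcm_get(s, "00280011", TRUE, "Columns")), integer(1)))
  px <- unique(vapply(slices, function(s) paste(
    dcm_get(s, "00280030", TRUE, "PixelSpacing"), collapse = ","),
    character(1)))
  if (length(rows) != 1 || length(cols) != 1 || length(px) != 1)
    stop("inconsistent in-plane geometry across slices")
  pos <- t(vapply(slices, function(s)
    dcm_get(s, "00200032", TRUE, "ImagePositionPatient"), numeric(3)))
  ord <- order(pos[, 3])
  pos <- pos[ord, , drop = FALSE]
  dz <- diff(pos[, 3])
  if (any(abs(dz - dz[1]) > 0.01))
    stop("nonuniform slice spacing beyond 0.01 mm tolerance")
  if (any(apply(pos[, 1:2, drop = FALSE], 2, function(v) diff(range(v))) > 1e-6))
    stop("slices are shifted in-plane; not a regular lattice")
  spacing <- c(as.numeric(strsplit(px, ",")[[1]]), dz[1])
  geo <- list(origin = pos[1, ], spacing = spacing,
              dims = c(rows, cols, length(files)),
              orientation = ori, frame_of_reference = fors[1])
  class(geo) <- "ct_geometry"
  geo
}

# Patient z coordinate of slice k (1-based), and inverse.
ct_slice_z <- function(ct, k) ct$origin[3] + (k - 1) * ct$spacing[3]
ct_nearest_slice <- function(ct, z) round((z - ct$origin[3]) / ct$spacing[3]) + 1

#' Read a DICOM RTSTRUCT structure set
#'
#' Contours are validated against the CT lattice: each must be closed-planar
#' with at least three vertices, lie on one CT slice plane (within half the
#' slice spacing) and fall inside the lattice extent.
#'
#' @param path RTSTRUCT file path.
#' @param ct a [read_ct_geometry()] result.
#' @return An object of class `structure_set`: a named list of ROIs, each
#'   with `name`, `number`, `color` (RGB 0-255) and `contours` (a list of
#'   Nx3 matrices of patient-mm vertices).
#' @export
read_structure_set <- function(path, ct) {
  ds <- read_dicom_file(path)
  ssr <- dcm_get(ds, "30060020", FALSE)
  if (is.null(ssr)) return(structure(list(), class = "structure_set"))
  rois <- list()
  for (item in ssr) {
    num <- as.integer(dcm_get(item, "30060022", TRUE, "ROINumber"))
    nm <- dcm_get(item, "30060026", TRUE, "ROIName")
    fr <- dcm_get(item, "30060024", FALSE)
    if (!is.null(fr) && !identical(fr, ct$frame_of_reference))
      stop("ROI '", nm, "' references a different frame of reference")
    rois[[as.character(num)]] <- list(name = nm, number = num,
                                      color = c(255, 255, 0),
                                      contours = list())
  }
  rcs <- dcm_get(ds, "30060039", FALSE)
  half_fov <- list(
    r = c(ct$origin[2] - ct$spacing[1] / 2,
          ct$origin[2] + (ct$dims[1] - 0.5) * ct$spacing[1]),
    c = c(ct$origin[1] - ct$spacing[2] / 2,
          ct$origin[1] + (ct$dims[2] - 0.5) * ct$spacing[2]))
  for (item in rcs) {
    ref <- as.character(as.integer(dcm_get(item, "30060084", TRUE,
                                           "ReferencedROINumber")))
    if (is.null(rois[[ref]])) stop("contour references unknown ROI ", ref)
    col <- dcm_get(item, "3006002A", FALSE)
    if (!is.null(col)) rois[[ref]]$color <- as.numeric(col)
    for (ci in dcm_get(item, "30060040", FALSE)) {
      gtype <- dcm_get(ci, "30060042", FALSE)
      if (!is.null(gtype) && !identical(gtype, "CLOSED_PLANAR"))
        stop("ROI '", rois[[ref]]$name, "': only CLOSED_PLANAR contours supported")
      cd <- dcm_get(ci, "30060050", TRUE, "ContourData")
      pts <- matrix(cd, ncol = 3, byrow = TRUE)
      if (nrow(pts) < 3)
        stop("ROI '", rois[[ref]]$name, "': contour with fewer than 3 vertices")
      if (diff(range(pts[, 3])) > 1e-6)
        stop("ROI '", rois[[ref]]$name, "': non-axial (non-planar) contour")
      z <- pts[1, 3]
      k <- ct_nearest_slice(ct, z)
      if (k < 1 || k > ct$dims[3] ||
          abs(z - ct_slice_z(ct, k)) > 0.5 * ct$spacing[3] + 1e-9)
        stop("ROI '", rois[[ref]]$name, "': contour off the CT lattice (z=", z, ")")
      if (min(pts[, 1]) < half_fov$c[1] || max(pts[, 1]) > half_fov$c[2] ||
          min(pts[, 2]) < half_fov$r[1] || max(pts[, 2]) > half_fov$r[2])
        stop("ROI '", rois[[ref]]$name, "': contour outside the CT lattice")
      rois[[ref]]$contours[[length(rois[[ref]]$contours) + 1]] <- pts
    }
  }
  out <- list()
  for (r in rois) {
    if (length(r$contours) == 0)
      warning("ROI '", r$name, "' has no contours; kept as empty")
    out[[r$name]] <- r
  }
  class(out) <- "structure_set"
  out
}

#' Read a DICOM RTPLAN
#'
#' Extracts the isocenter, and per beam the control points (gantry angle,
#' cumulative meterset weight, jaw and MLC positions, collimator angle) plus
#' the MLC leaf boundaries. Jaw/MLC positions omitted at later control
#' points are carried forward from the previous one, as DICOM allows.
#'
#' @param path RTPLAN file path.
#' @return An object of class `plan_info`: `isocenter` (patient mm),
#'   `beams` (list; each with `number`, `name`, `energy`,
#'   `leaf_boundaries`, `collimator_deg`, `direction` and `control_points`,
#'   a list of `list(index, gantry_deg, cum_weight, jaw_x, jaw_y, mlc)` with
#'   `mlc` a 2-row matrix, row 1 = bank A (left leaf tips), row 2 = bank B).
#' @export
read_plan <- function(path) {
  ds <- read_dicom_file(path)
  bs <- dcm_get(ds, "300A00B0", TRUE, "BeamSequence")
  if (length(bs) < 1) stop("plan has no beams")
  beams <- list()
  iso <- NULL
  for (b in bs) {
    num <- as.integer(dcm_get(b, "300A00C0", TRUE, "BeamNumber"))
    nm <- dcm_get(b, "300A00C2", FALSE)
    bname <- if (is.null(nm)) paste0("beam", num) else nm
    bld <- dcm_get(b, "300A00B6", FALSE)
    leaf_bounds <- NULL
    for (d in bld) {
      if (identical(dcm_get(d, "300A00B8", FALSE), "MLCX"))
        leaf_bounds <- dcm_get(d, "300A00BE", FALSE)
    }
    cps_raw <- dcm_get(b, "300A0111", TRUE, "ControlPointSequence")
    if (length(cps_raw) < 2)
      stop("beam '", bname, "' has fewer than two control points")
    energy <- NA_real_; coll <- 0; direction <- "NONE"
    jaw_x <- NULL; jaw_y <- NULL; mlc <- NULL
    cps <- vector("list", length(cps_raw))
    for (i in seq_along(cps_raw)) {
      cp <- cps_raw[[i]]
      e <- dcm_get(cp, "300A0114", FALSE); if (!is.null(e)) energy <- e
      ic <- dcm_get(cp, "300A012C", FALSE); if (!is.null(ic)) iso <- ic
      cd <- dcm_get(cp, "300A0120", FALSE); if (!is.null(cd)) coll <- cd
      dir <- dcm_get(cp, "300A011F", FALSE); if (!is.null(dir) && nzchar(dir))
        direction <- dir
      for (p in dcm_get(cp, "300A011A", FALSE)) {
        type <- dcm_get(p, "300A00B8", TRUE, "RTBeamLimitingDeviceType")
        pos <- dcm_get(p, "300A011C", TRUE, "LeafJawPositions")
        if (type %in% c("X", "ASYMX")) jaw_x <- pos
        else if (type %in% c("Y", "ASYMY")) jaw_y <- pos
        else if (type == "MLCX") mlc <- matrix(pos, nrow = 2, byrow = TRUE)
      }
      if (i == 1 && (is.null(jaw_x) || is.null(jaw_y)))
        stop("beam '", bname, "': first control point lacks jaw positions")
      cps[[i]] <- list(
        index = as.integer(dcm_get(cp, "300A0112", TRUE, "ControlPointIndex")),
        gantry_deg = as.numeric(dcm_get(cp, "300A011E", TRUE, "GantryAngle")),
        cum_weight = as.numeric(dcm_get(cp, "300A0134", TRUE,
                                        "CumulativeMetersetWeight")),
        jaw_x = jaw_x, jaw_y = jaw_y, mlc = mlc)
    }
    w <- vapply(cps, `[[`, numeric(1), "cum_weight")
    if (is.unsorted(w)) stop("beam '", bname,
                             "': control points not sorted by meterset")
    if (!is.null(mlc) && ncol(mlc) + 1 != length(leaf_bounds))
      stop("beam '", bname, "': leaf boundaries inconsistent with leaf count")
    beams[[length(beams) + 1]] <- list(
      number = num, name = bname, energy = energy,
      collimator_deg = as.numeric(coll), direction = direction,
      leaf_boundaries = leaf_bounds, control_points = cps)
  }
  if (is.null(iso)) stop("plan has no isocenter position")
  out <- list(isocenter = as.numeric(iso), beams = beams)
  class(out) <- "plan_info"
  out
}

#' Gantry-angle span of an arc beam
#'
#' Unwraps the control-point gantry angles (using the rotation direction)
#' and returns the total traveled span in degrees.
#'
#' @param beam one element of `plan_info$beams`.
#' @return Angular span, degrees (positive).
#' @export
beam_arc_span <- function(beam) {
  a <- vapply(beam$control_points, `[[`, numeric(1), "gantry_deg")
  d <- diff(a)
  d <- d %% 360
  if (identical(beam$direction, "CC")) d <- d - 360
  else d[d > 180] <- d[d > 180] - 360   # no/unknown direction: shortest path
  abs(sum(d))
}

#' Map patient coordinates to the treatment-room frame
#'
#' Room coordinates are centimeters with the plan isocenter at the origin:
#' X lateral, Y longitudinal (gun-target), Z vertical. For identity
#' (head-first supine) orientation the mapping is `X = (px - ix)/10`,
#' `Y = (pz - iz)/10`, `Z = -(py - iy)/10` (patient +y points posterior,
#' i.e. downward when supine).
#'
#' @param xyz_mm Nx3 matrix (or length-3 vector) of patient coordinates, mm.
#' @param isocenter_mm plan isocenter, patient mm.
#' @return Nx3 matrix (or vector) of room coordinates, cm.
#' @export
patient_to_room <- function(xyz_mm, isocenter_mm) {
  v <- FALSE
  if (is.null(dim(xyz_mm))) { xyz_mm <- matrix(xyz_mm, ncol = 3); v <- TRUE }
  d <- sweep(xyz_mm, 2, isocenter_mm)
  out <- cbind(d[, 1], d[, 3], -d[, 2]) / 10
  colnames(out) <- c("x", "y", "z")
  if (v) out[1, ] else out
}

# ---- synthetic fixture writer ---------------------------------------------

fixture_uid <- function(seed, kind, n) paste(UID_ROOT, seed, kind, n, sep = ".")

#' Write a synthetic CT + RTSTRUCT + RTPLAN fixture suite
#'
#' Generates a minimal, standards-readable DICOM fixture set emulating a TPS
#' export for phantom geometries: a CT series on a regular lattice, sphere
#' and cylinder ROIs contoured slice by slice, and an arc plan with jaws,
#' MLC and control points at constant gantry speed. All UIDs derive
#' deterministically from `spec$seed`, so writing the same spec twice gives
#' byte-identical files.
#'
#' @param spec a list:
#'   \describe{
#'     \item{ct}{`list(dims = c(rows, cols, slices), spacing = c(row, col,
#'       slice) mm, origin = c(x, y, z) mm)`}
#'     \item{rois}{list of `list(name, color = c(r, g, b), shape = "sphere"
#'       or "cylinder", center = patient mm, radius_mm, [length_mm])`}
#'     \item{isocenter}{patient mm}
#'     \item{beams}{list of `list(name, start_deg, span_deg, direction =
#'       "CW"|"CC", speed_dps, field_mm = c(x, y), collimator_deg, n_ctrl,
#'       energy)`}
#'     \item{seed}{integer, determines all UIDs}
#'   }
#' @param dir output directory (created if needed).
#' @return Invisibly, a list with the written file paths: `ct` (vector),
#'   `rtstruct`, `rtplan`.
#' @export
write_fixture_suite <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- spec$seed %||% 1L
  ct <- spec$ct
  stopifnot(length(ct$dims) == 3, length(ct$spacing) == 3,
            length(ct$origin) == 3)
  for (r in spec$rois) check_roi_in_grid(r, ct)
  study <- fixture_uid(seed, 1, 0)
  frame <- fixture_uid(seed, 2, 0)
  series <- fixture_uid(seed, 3, 0)

  ct_files <- character(ct$dims[3])
  for (k in seq_len(ct$dims[3])) {
    z <- ct$origin[3] + (k - 1) * ct$spacing[3]
    sop <- fixture_uid(seed, 4, k)
    img <- fixture_ct_pixels(ct, spec$rois, z)
    dsel <- list(
      dcm_el(0x0008, 0x0016, "UI", str_payload(SOP_CLASS[["ct"]], TRUE)),
      dcm_el(0x0008, 0x0018, "UI", str_payload(sop, TRUE)),
      dcm_el(0x0008, 0x0020, "DA", str_payload("20260101")),
      dcm_el(0x0008, 0x0060, "CS", str_payload("CT")),
      dcm_el(0x0010, 0x0010, "PN", str_payload("PHANTOM^SYNTH")),
      dcm_el(0x0010, 0x0020, "LO", str_payload("SYNTH001")),
      dcm_el(0x0018, 0x0050, "DS", ds_payload(ct$spacing[3])),
      dcm_el(0x0020, 0x000D, "UI", str_payload(study, TRUE)),
      dcm_el(0x0020, 0x000E, "UI", str_payload(series, TRUE)),
      dcm_el(0x0020, 0x0013, "IS", is_payload(k)),
      dcm_el(0x0020, 0x0032, "DS", ds_payload(c(ct$origin[1:2], z))),
      dcm_el(0x0020, 0x0037, "DS", ds_payload(c(1, 0, 0, 0, 1, 0))),
      dcm_el(0x0020, 0x0052, "UI", str_payload(frame, TRUE)),
      dcm_el(0x0028, 0x0002, "US", u16le(1)),
      dcm_el(0x0028, 0x0004, "CS", str_payload("MONOCHROME2")),
      dcm_el(0x0028, 0x0010, "US", u16le(ct$dims[1])),
      dcm_el(0x0028, 0x0011, "US", u16le(ct$dims[2])),
      dcm_el(0x0028, 0x0030, "DS", ds_payload(ct$spacing[1:2])),
      dcm_el(0x0028, 0x0100, "US", u16le(16)),
      dcm_el(0x0028, 0x0101, "US", u16le(16)),
      dcm_el(0x0028, 0x0102, "US", u16le(15)),
      dcm_el(0x0028, 0x0103, "US", u16le(0)),
      dcm_el(0x7FE0, 0x0010, "OW", u16le(img))
    )
    f <- file.path(dir, sprintf("ct_%03d.dcm", k))
    write_dicom_file(f, SOP_CLASS[["ct"]], sop, dsel)
    ct_files[k] <- f
  }

  rs_file <- file.path(dir, "rtstruct.dcm")
  write_rtstruct_fixture(rs_file, spec, ct, seed, study, frame)
  rp_file <- file.path(dir, "rtplan.dcm")
  write_rtplan_fixture(rp_file, spec, seed, study)
  invisible(list(ct = ct_files, rtstruct = rs_file, rtplan = rp_file))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_roi_in_grid <- function(roi, ct) {
  lo <- roi$center - roi$radius_mm
  hi <- roi$center + roi$radius_mm
  gmin <- ct$origin - 0.5 * ct$spacing[c(2, 1, 3)]
  gmax <- ct$origin + (ct$dims[c(2, 1, 3)] - 0.5) * ct$spacing[c(2, 1, 3)]
  if (any(lo < gmin) || any(hi > gmax))
    stop("ROI '", roi$name, "' extends outside the CT grid")
}

# Slice pixel values: low background, bright shapes (for visual sanity only;
# readers use geometry tags, not pixel values).
fixture_ct_pixels <- function(ct, rois, z) {
  rows <- ct$dims[1]; cols <- ct$dims[2]
  xs <- ct$origin[1] + (seq_len(cols) - 1) * ct$spacing[2]
  ys <- ct$origin[2] + (seq_len(rows) - 1) * ct$spacing[1]
  img <- matrix(100L, nrow = rows, ncol = cols)
  for (r in rois) {
    dz2 <- (z - r$center[3])^2
    if (identical(r$shape %||% "sphere", "sphere")) {
      if (dz2 > r$radius_mm^2) next
      rs2 <- r$radius_mm^2 - dz2
    } else {
      if (abs(z - r$center[3]) > (r$length_mm %||% 0) / 2) next
      rs2 <- r$radius_mm^2
    }
    d2 <- outer((ys - r$center[2])^2, (xs - r$center[1])^2, `+`)
    img[d2 <= rs2] <- 3000L
  }
  # column-major over rows = DICOM row-major needs transpose
  as.integer(t(img))
}

# Circle polygon on an axial plane, n vertices, closed implicitly.
circle_polygon <- function(cx, cy, z, radius, n = 72) {
  a <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + radius * cos(a), cy + radius * sin(a), z)
}

roi_slice_polygons <- function(roi, ct) {
  out <- list()
  for (k in seq_len(ct$dims[3])) {
    z <- ct_slice_z(ct, k)
    shape <- roi$shape %||% "sphere"
    if (shape == "sphere") {
      dz2 <- (z - roi$center[3])^2
      if (dz2 >= roi$radius_mm^2) next
      rs <- sqrt(roi$radius_mm^2 - dz2)
      if (rs < 0.25) next
    } else {
      if (abs(z - roi$center[3]) > (roi$length_mm %||% 0) / 2) next
      rs <- roi$radius_mm
    }
    out[[length(out) + 1]] <- circle_polygon(roi$center[1], roi$center[2], z, rs)
  }
  out
}

write_rtstruct_fixture <- function(path, spec, ct, seed, study, frame) {
  sop <- fixture_uid(seed, 5, 0)
  ssroi_items <- list(); rc_items <- list()
  for (i in seq_along(spec$rois)) {
    roi <- spec$rois[[i]]
    ssroi_items[[i]] <- list(
      dcm_el(0x3006, 0x0022, "IS", is_payload(i)),
      dcm_el(0x3006, 0x0024, "UI", str_payload(frame, TRUE)),
      dcm_el(0x3006, 0x0026, "LO", str_payload(roi$name)))
    polys <- roi_slice_polygons(roi, ct)
    cseq <- lapply(polys, function(p) list(
      dcm_el(0x3006, 0x0042, "CS", str_payload("CLOSED_PLANAR")),
      dcm_el(0x3006, 0x0046, "IS", is_payload(nrow(p))),
      dcm_el(0x3006, 0x0050, "DS", ds_payload(as.numeric(t(p))))))
    rc_items[[i]] <- list(
      dcm_el(0x3006, 0x002A, "IS", is_payload(roi$color %||% c(255, 255, 0))),
      dcm_el(0x3006, 0x0040, "SQ", cseq),
      dcm_el(0x3006, 0x0084, "IS", is_payload(i)))
  }
  dsel <- list(
    dcm_el(0x0008, 0x0016, "UI", str_payload(SOP_CLASS[["rtstruct"]], TRUE)),
    dcm_el(0x0008, 0x0018, "UI", str_payload(sop, TRUE)),
    dcm_el(0x0008, 0x0060, "CS", str_payload("RTSTRUCT")),
    dcm_el(0x0010, 0x0010, "PN", str_payload("PHANTOM^SYNTH")),
    dcm_el(0x0010, 0x0020, "LO", str_payload("SYNTH001")),
    dcm_el(0x0020, 0x000D, "UI", str_payload(study, TRUE)),
    dcm_el(0x3006, 0x0002, "SH", str_payload("SYNTH")),
    dcm_el(0x3006, 0x0020, "SQ", ssroi_items),
    dcm_el(0x3006, 0x0039, "SQ", rc_items)
  )
  write_dicom_file(path, SOP_CLASS[["rtstruct"]], sop, dsel)
}

write_rtplan_fixture <- function(path, spec, seed, study) {
  sop <- fixture_uid(seed, 6, 0)
  beam_items <- list()
  for (bi in seq_along(spec$beams)) {
    b <- spec$beams[[bi]]
    n_ctrl <- b$n_ctrl %||% 19L
    fx <- b$field_mm[1] / 2; fy <- b$field_mm[2] / 2
    n_pairs <- 40L
    bounds <- seq(-200, 200, length.out = n_pairs + 1)
    # leaves open to the jaw-defined field
    bank_a <- rep(-fx, n_pairs); bank_b <- rep(fx, n_pairs)
    closed <- bounds[-1] <= -fy | bounds[-(n_pairs + 1)] >= fy
    bank_a[closed] <- 0; bank_b[closed] <- 0
    sgn <- if (identical(b$direction %||% "CW", "CC")) -1 else 1
    angles <- wrap_angle(b$start_deg + sgn * seq(0, b$span_deg,
                                                 length.out = n_ctrl + 1))
    weights <- seq(0, 1, length.out = n_ctrl + 1)
    cps <- vector("list", n_ctrl + 1)
    for (i in seq_len(n_ctrl + 1)) {
      el <- list(dcm_el(0x300A, 0x0112, "IS", is_payload(i - 1)))
      if (i == 1) {
        el <- c(el, list(
          dcm_el(0x300A, 0x0114, "DS", ds_payload(b$energy %||% 6)),
          dcm_el(0x300A, 0x011A, "SQ", list(
            list(dcm_el(0x300A, 0x00B8, "CS", str_payload("ASYMX")),
                 dcm_el(0x300A, 0x011C, "DS", ds_payload(c(-fx, fx)))),
            list(dcm_el(0x300A, 0x00B8, "CS", str_payload("ASYMY")),
                 dcm_el(0x300A, 0x011C, "DS", ds_payload(c(-fy, fy)))),
            list(dcm_el(0x300A, 0x00B8, "CS", str_payload("MLCX")),
                 dcm_el(0x300A, 0x011C, "DS",
                        ds_payload(c(bank_a, bank_b))))))))
      }
      el <- c(el, list(dcm_el(0x300A, 0x011E, "DS", ds_payload(angles[i]))))
      if (i == 1) {
        el <- c(el, list(
          dcm_el(0x300A, 0x011F, "CS", str_payload(b$direction %||% "CW")),
          dcm_el(0x300A, 0x0120, "DS", ds_payload(b$collimator_deg %||% 0)),
          dcm_el(0x300A, 0x012C, "DS", ds_payload(spec$isocenter))))
      }
      el <- c(el, list(dcm_el(0x300A, 0x0134, "DS", ds_payload(weights[i]))))
      cps[[i]] <- el
    }
    beam_items[[bi]] <- list(
      dcm_el(0x300A, 0x00B6, "SQ", list(
        list(dcm_el(0x300A, 0x00B8, "CS", str_payload("ASYMX")),
             dcm_el(0x300A, 0x00BC, "IS", is_payload(1))),
        list(dcm_el(0x300A, 0x00B8, "CS", str_payload("ASYMY")),
             dcm_el(0x300A, 0x00BC, "IS", is_payload(1))),
        list(dcm_el(0x300A, 0x00B8, "CS", str_payload("MLCX")),
             dcm_el(0x300A, 0x00BC, "IS", is_payload(n_pairs)),
             dcm_el(0x300A, 0x00BE, "DS", ds_payload(bounds))))),
      dcm_el(0x300A, 0x00C0, "IS", is_payload(bi)),
      dcm_el(0x300A, 0x00C2, "LO", str_payload(b$name %||% paste0("ARC", bi))),
      dcm_el(0x300A, 0x010E, "DS", ds_payload(1)),
      dcm_el(0x300A, 0x0110, "IS", is_payload(n_ctrl + 1)),
      dcm_el(0x300A, 0x0111, "SQ", cps))
  }
  dsel <- list(
    dcm_el(0x0008, 0x0016, "UI", str_payload(SOP_CLASS[["rtplan"]], TRUE)),
    dcm_el(0x0008, 0x0018, "UI", str_payload(sop, TRUE)),
    dcm_el(0x0008, 0x0060, "CS", str_payload("RTPLAN")),
    dcm_el(0x0010, 0x0010, "PN", str_payload("PHANTOM^SYNTH")),
    dcm_el(0x0010, 0x0020, "LO", str_payload("SYNTH001")),
    dcm_el(0x0020, 0x000D, "UI", str_payload(study, TRUE)),
    dcm_el(0x300A, 0x0002, "SH", str_payload("SYNTHPLAN")),
    dcm_el(0x300A, 0x00B0, "SQ", beam_items)
  )
  write_dicom_file(path, SOP_CLASS[["rtplan"]], sop, dsel)
}
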