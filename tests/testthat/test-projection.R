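make_ct <- function(dims = c(32, 32, 16), spacing = c(1, 1, 1),
                    origin = NULL) {
  if (is.null(origin))
    origin <- -c((dims[2] - 1) / 2 * spacing[2], (dims[1] - 1) / 2 * spacing[1],
                 (dims[3] - 1) / 2 * spacing[3])
  structure(list(origin = origin, spacing = spacing, dims = as.integer(dims),
                 orientation = c(1, 0, 0, 0, 1, 0),
                 frame_of_reference = "x"), class = "ct_geometry")
}

square_contour <- function(cx, cy, z, half) {
  rbind(c(cx - half, cy - half, z), c(cx + half, cy - half, z),
        c(cx + half, cy + half, z), c(cx - half, cy + half, z))
}

test_that("voxelization matches a brute-force point-in-polygon oracle", {
  ct <- make_ct(c(24, 24, 5))
  # axis-aligned 10 x 10 mm square on one slice, 1 mm voxels
  pts <- square_contour(0.2, -0.3, 0, 5)
  g <- voxelize_roi(list(pts), ct)
  expect_equal(sum(g$occ), 100, tolerance = 0.2)  # ~100 voxels
  # oracle comparison over every voxel of the slice
  k <- ct_nearest <- round((0 - ct$origin[3]) / ct$spacing[3]) + 1
  xs <- ct$origin[1] + (seq_len(ct$dims[2]) - 1) * ct$spacing[2]
  ys <- ct$origin[2] + (seq_len(ct$dims[1]) - 1) * ct$spacing[1]
  for (i in seq_len(ct$dims[1])) for (j in seq_len(ct$dims[2]))
    expect_identical(g$occ[i, j, k],
                     oracle_pip(xs[j], ys[i], pts[, 1:2]))
  # irregular polygon
  poly <- cbind(c(-6, 4, 7, 0, -5), c(-5, -7, 2, 6, 3), 1)
  g2 <- voxelize_roi(list(poly), ct)
  k2 <- round((1 - ct$origin[3]) / ct$spacing[3]) + 1
  for (i in seq_len(ct$dims[1])) for (j in seq_len(ct$dims[2]))
    expect_identical(g2$occ[i, j, k2],
                     oracle_pip(xs[j], ys[i], poly[, 1:2]))
})

test_that("empty and degenerate ROIs voxelize predictably", {
  ct <- make_ct()
  g <- voxelize_roi(list(), ct)
  expect_false(any(g$occ))
  expect_error(voxelize_roi(list(square_contour(0, 0, 100, 2)), ct), "outside")
  expect_error(voxelize_roi(list(matrix(c(0, 0, 0, 1, 1, 0), 2, byrow = TRUE)),
                            ct), "fewer than 3")
})

test_that("sphere voxelization volume approaches the analytic volume", {
  # 8-mm-diameter sphere on the 0.5/0.5/1.0 mm validation lattice
  spec <- bb_fixture(center = c(0, 0, 0), iso = c(0, 0, 0))
  d <- withr::local_tempdir()
  files <- write_fixture_suite(spec, d)
  ct <- read_ct_geometry(files$ct)
  ss <- read_structure_set(files$rtstruct, ct)
  g <- voxelize_roi(ss$BB, ct)
  vol <- sum(g$occ) * prod(ct$spacing)
  expect_equal(vol, 4 / 3 * pi * 4^3, tolerance = 0.1)
})

test_that("isotropic dilation honors physical distance on anisotropic voxels", {
  ct <- make_ct(c(15, 15, 15), spacing = c(1, 1, 1))
  g <- voxelize_roi(list(), ct)
  g$occ[8, 8, 8] <- TRUE
  d0 <- dilate_isotropic(g, 0)
  expect_identical(d0$occ, g$occ)
  d5 <- dilate_isotropic(g, 5)
  # brute-force distance scan
  cnt <- 0
  for (i in 1:15) for (j in 1:15) for (k in 1:15) {
    inside <- (i - 8)^2 + (j - 8)^2 + (k - 8)^2 <= 25 + 1e-9
    expect_identical(d5$occ[i, j, k], inside)
    cnt <- cnt + inside
  }
  expect_equal(cnt, 515)
  expect_true(all(d5$occ[g$occ]))  # monotone
  # anisotropic: 2 mm slices reach fewer planes
  ct2 <- make_ct(c(11, 11, 11), spacing = c(1, 1, 2))
  g2 <- voxelize_roi(list(), ct2); g2$occ[6, 6, 6] <- TRUE
  d2 <- dilate_isotropic(g2, 5)
  expect_true(d2$occ[6, 6, 8])    # 4 mm away along slices
  expect_false(d2$occ[6, 6, 9])   # 6 mm away
})

test_that("ray casting equals the scalar first-hit oracle on small grids", {
  geom <- linac_geometry()
  ct <- make_ct(c(20, 20, 10), spacing = c(1.5, 1.5, 2))
  set.seed(4)
  g <- voxelize_roi(list(), ct)
  # random blobby occupancy
  idx <- cbind(sample(6:15, 40, TRUE), sample(6:15, 40, TRUE),
               sample(3:8, 40, TRUE))
  g$occ[idx] <- TRUE
  iso <- c(0, 0, 0)
  for (th in c(0, 33.5, 90, 181, 267.5)) {
    m <- raycast_projection(g, th, iso, geom)
    w <- which(m$pixels, arr.ind = TRUE)
    expect_gt(nrow(w), 0)
    # every set pixel confirmed by the oracle
    for (r in seq_len(min(nrow(w), 25)))
      expect_true(oracle_raycast_pixel(w[r, 2] - 1, w[r, 1] - 1, g, th, iso,
                                       geom))
    # pixels just outside the hit region confirmed empty
    box_c <- range(w[, 2]); box_r <- range(w[, 1])
    ring <- rbind(
      cbind(box_r[1] - 3, seq(box_c[1] - 3, box_c[2] + 3, by = 2)),
      cbind(box_r[2] + 3, seq(box_c[1] - 3, box_c[2] + 3, by = 2)),
      cbind(seq(box_r[1] - 3, box_r[2] + 3, by = 2), box_c[1] - 3),
      cbind(seq(box_r[1] - 3, box_r[2] + 3, by = 2), box_c[2] + 3))
    ring <- ring[ring[, 1] >= 1 & ring[, 1] <= 512 &
                 ring[, 2] >= 1 & ring[, 2] <= 512, , drop = FALSE]
    for (r in seq_len(nrow(ring))) {
      expect_false(m$pixels[ring[r, 1], ring[r, 2]])
      expect_false(oracle_raycast_pixel(ring[r, 2] - 1, ring[r, 1] - 1, g,
                                        th, iso, geom))
    }
    # full-map equality with the oracle on the bounding window
    for (r in seq(box_r[1] - 1, box_r[2] + 1, by = 3))
      for (c in seq(box_c[1] - 1, box_c[2] + 1, by = 3))
        expect_identical(m$pixels[r, c],
                         oracle_raycast_pixel(c - 1, r - 1, g, th, iso, geom))
  }
})

test_that("an 8-mm sphere at the isocenter projects to a 16-pixel disk", {
  geom <- linac_geometry()
  spec <- bb_fixture(center = c(0, 0, 0), iso = c(0, 0, 0))
  d <- withr::local_tempdir()
  files <- write_fixture_suite(spec, d)
  ct <- read_ct_geometry(files$ct)
  ss <- read_structure_set(files$rtstruct, ct)
  g <- voxelize_roi(ss$BB, ct)
  for (th in c(0, 45.5, 123, 270)) {
    m <- raycast_projection(g, th, c(0, 0, 0), geom)
    w <- which(m$pixels, arr.ind = TRUE)
    # AB diameter: 8 mm / 0.5 mm binned pixels = 16 +/- 1
    expect_equal(diff(range(w[, 2])) + 1, 16, tolerance = 1 / 16)
    ov <- extract_contour(m)
    expect_equal(unname(ov$centroid), c(255.5, 255.5), tolerance = 0.5)
    # convex ROI: projection has no holes (all rows between extremes filled)
    for (r in unique(w[, 1])) {
      cc <- sort(w[w[, 1] == r, 2])
      expect_equal(cc, seq(min(cc), max(cc)))
    }
  }
  # empty grid projects to an empty map
  g0 <- voxelize_roi(list(), ct)
  expect_false(any(raycast_projection(g0, 10, c(0, 0, 0), geom)$pixels))
})

test_that("contour extraction follows the 8-neighbor + map-border rule", {
  # single pixel
  m <- matrix(FALSE, 512, 512); m[100, 200] <- TRUE
  ov <- extract_contour(m)
  expect_equal(unname(ov$boundary), cbind(199, 99))
  expect_equal(unname(ov$centroid), c(199, 99))
  # solid 3x3 block: 8 perimeter pixels, center excluded
  m2 <- matrix(FALSE, 64, 64); m2[10:12, 20:22] <- TRUE
  ov2 <- extract_contour(m2)
  expect_equal(nrow(ov2$boundary), 8)
  expect_false(any(ov2$boundary[, 1] == 20 & ov2$boundary[, 2] == 10))
  # all-ones map: exactly the border pixels
  m3 <- matrix(TRUE, 16, 16)
  ov3 <- extract_contour(m3)
  expect_equal(nrow(ov3$boundary), 4 * 16 - 4)
  # oracle equivalence on random masks
  set.seed(9)
  for (rep in 1:5) {
    mm <- matrix(stats::runif(32 * 32) < 0.4, 32, 32)
    got <- extract_contour(mm)$boundary
    want <- which(oracle_boundary(mm), arr.ind = TRUE)
    want <- cbind(column = want[, 2] - 1, row = want[, 1] - 1)
    want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
    expect_equal(unname(got), unname(want))
  }
  # empty map: flagged empty centroid
  ov4 <- extract_contour(matrix(FALSE, 8, 8))
  expect_true(ov4$empty)
  expect_null(ov4$centroid)
})

test_that("contour extraction is idempotent on reconstructed boundaries", {
  set.seed(2)
  mm <- matrix(FALSE, 40, 40); mm[10:25, 12:30] <- TRUE
  b1 <- extract_contour(mm)$boundary
  mask <- matrix(FALSE, 40, 40)
  mask[cbind(b1[, "row"] + 1, b1[, "column"] + 1)] <- TRUE
  b2 <- extract_contour(mask)$boundary
  expect_equal(unname(b2), unname(b1))  # a 1-px ring is its own boundary
})

test_that("precomputed sets cover the angle grid and agree with direct casts", {
  set <- get_bb_projection_set()
  expect_length(set$rois$BB$overlays, 720)
  expect_equal(set$angle_step_deg, 0.5)
  expect_equal(set$rois$BB$overlays[[1]]$theta_deg, 0)
  expect_equal(set$rois$BB$overlays[[720]]$theta_deg, 359.5)
  # consistency with an on-the-fly projection at sampled angles
  cfg <- sim_preset("bb-validation", speed_dps = 1.5, seed = 1)
  d <- file.path(tempdir(), "cinemv_bb_fixture")
  ct <- read_ct_geometry(list.files(d, pattern = "^ct_", full.names = TRUE))
  ss <- read_structure_set(file.path(d, "rtstruct.dcm"), ct)
  pl <- read_plan(file.path(d, "rtplan.dcm"))
  g <- voxelize_roi(ss$BB, ct)
  for (th in c(0, 90.5, 200)) {
    direct <- extract_contour(raycast_projection(g, th, pl$isocenter,
                                                 linac_geometry()),
                              ss$BB$color)
    stored <- lookup_overlay(set, "BB", th)
    expect_equal(unname(stored$boundary), unname(direct$boundary))
    expect_equal(stored$centroid, direct$centroid)
  }
})

test_that("translating the ROI moves the centroid per the projection model", {
  geom <- linac_geometry()
  ct <- make_ct(c(40, 40, 12), spacing = c(1, 1, 1))
  iso <- c(0, 0, 0)
  mk <- function(cx) {
    g <- voxelize_roi(list(square_contour(cx, 0, 0, 4),
                           square_contour(cx, 0, 1, 4),
                           square_contour(cx, 0, -1, 4)), ct)
    g
  }
  for (th in c(20, 110, 300)) {
    c1 <- extract_contour(raycast_projection(mk(0), th, iso, geom))$centroid
    c2 <- extract_contour(raycast_projection(mk(8), th, iso, geom))$centroid
    # expected shift: u(0.8 cm object) - u(0), via the closed form, in
    # binned pixels
    du_mm <- 10 * (oracle_u_lateral(0.8, th) - 0)
    expect_equal(c2[["column"]] - c1[["column"]], du_mm / 0.5, tolerance = 1)
  }
})

test_that("overlay lookup picks the nearest grid angle, wrap-aware", {
  set <- get_bb_projection_set()
  expect_equal(lookup_overlay(set, "BB", 10.0)$theta_deg, 10.0)
  expect_equal(lookup_overlay(set, "BB", 10.24)$theta_deg, 10.0)
  expect_equal(lookup_overlay(set, "BB", 10.26)$theta_deg, 10.5)
  expect_equal(lookup_overlay(set, "BB", 10.25)$theta_deg, 10.0)  # tie: lower
  expect_equal(lookup_overlay(set, "BB", 359.9)$theta_deg, 0.0)
  expect_equal(lookup_overlay(set, "BB", -0.2)$theta_deg, 0.0)
  expect_equal(lookup_overlay(set, "BB", -0.3)$theta_deg, 359.5)
  expect_error(lookup_overlay(set, "nope", 0), "unknown ROI")
})

test_that("projection sets survive a save/load round trip losslessly", {
  set <- get_bb_projection_set()
  f <- tempfile(fileext = ".json")
  save_projection_set(set, f)
  set2 <- load_projection_set(f)
  expect_equal(set2$angle_step_deg, set$angle_step_deg)
  for (i in c(1, 100, 401, 720)) {
    a <- set$rois$BB$overlays[[i]]; b <- set2$rois$BB$overlays[[i]]
    expect_equal(unname(b$boundary), unname(a$boundary))
    expect_identical(b$centroid, a$centroid)
    expect_equal(b$theta_deg, a$theta_deg)
  }
  bogus <- tempfile(fileext = ".json")
  jsonlite::write_json(list(container = "something-else"), bogus,
                       auto_unbox = TRUE)
  expect_error(load_projection_set(bogus), "container")
})

test_that("field eligibility verdicts follow the aperture extent", {
  geom <- linac_geometry()
  mkplan <- function(field_mm, coll = 0) {
    spec <- bb_fixture()
    spec$beams[[1]]$field_mm <- field_mm
    spec$beams[[1]]$collimator_deg <- coll
    d <- withr::local_tempdir(.local_envir = parent.frame())
    read_plan(write_fixture_suite(spec, d)$rtplan)
  }
  # 10 x 10 cm centered field with 5 mm margin: passes everywhere
  r10 <- field_within_epid(mkplan(c(100, 100)), geom, margin_mm = 5)
  expect_true(all(r10$pass))
  # 24 x 24 cm + 5 mm: 120 + 5 <= 128 mm, still eligible
  r24 <- field_within_epid(mkplan(c(240, 240)), geom, margin_mm = 5)
  expect_true(all(r24$pass))
  # 26 x 26 cm exceeds the 25.6 cm field of view
  r26 <- field_within_epid(mkplan(c(260, 260)), geom, margin_mm = 5)
  expect_false(any(r26$pass))
  # collimator rotation can push a passing field out: 24 cm at 45 deg has
  # corner extent 12 * sqrt(2) cm > 12.8 cm
  r45 <- field_within_epid(mkplan(c(240, 240), coll = 45), geom, margin_mm = 5)
  expect_false(any(r45$pass))
})
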