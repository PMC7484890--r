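test_that("CT geometry round-trips through the fixture writer", {
  # planning-CT parameters of a clinical series: 1.2 x 1.2 mm in-plane,
  # 3 mm slices
  spec <- bb_fixture(center = c(0, 0, 0), radius = 4, iso = c(0, 0, 0),
                     spacing = c(1.2, 1.2, 3.0), pad = c(16, 16, 12))
  d <- withr::local_tempdir()
  files <- write_fixture_suite(spec, d)
  ct <- read_ct_geometry(files$ct)
  expect_equal(ct$dims, spec$ct$dims)
  expect_equal(ct$spacing, c(1.2, 1.2, 3.0))
  expect_equal(ct$origin, spec$ct$origin)
  # shuffled file order yields the same geometry
  ct2 <- read_ct_geometry(rev(files$ct))
  expect_equal(ct2, ct)
  expect_error(read_ct_geometry(files$ct[1]), "two slices")
})

test_that("structure sets round-trip with names, colors and slice counts", {
  spec <- bb_fixture()
  d <- withr::local_tempdir()
  files <- write_fixture_suite(spec, d)
  ct <- read_ct_geometry(files$ct)
  ss <- read_structure_set(files$rtstruct, ct)
  expect_named(ss, "BB")
  expect_equal(ss$BB$color, c(255, 0, 0))
  # a 4-mm-radius sphere on 1-mm slices spans several planes
  expect_gte(length(ss$BB$contours), 2)
  zs <- vapply(ss$BB$contours, function(p) p[1, 3], numeric(1))
  expect_true(all(abs(zs - round(zs - spec$ct$origin[3]) - spec$ct$origin[3])
                  < 1e-9))
  # each contour is planar and closed with >= 3 vertices
  for (p in ss$BB$contours) {
    expect_gte(nrow(p), 3)
    expect_lt(diff(range(p[, 3])), 1e-9)
  }
})

test_that("sphere contour areas match the analytic circle sections", {
  spec <- bb_fixture(center = c(-100, 0, 0), radius = 4)
  d <- withr::local_tempdir()
  files <- write_fixture_suite(spec, d)
  ct <- read_ct_geometry(files$ct)
  ss <- read_structure_set(files$rtstruct, ct)
  for (p in ss$BB$contours) {
    dz <- p[1, 3] - spec$rois[[1]]$center[3]
    expected <- pi * (16 - dz^2)
    # shoelace area
    x <- p[, 1]; y <- p[, 2]
    a <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
    expect_equal(a, expected, tolerance = 0.05)
  }
})

test_that("plans round-trip isocenter, control points and arc span", {
  spec <- bb_fixture(iso = c(10, 0, 50))
  spec$beams <- list(
    list(name = "ARC1", start_deg = 180, span_deg = 360, direction = "CW",
         speed_dps = 1.5, field_mm = c(240, 240), collimator_deg = 0,
         n_ctrl = 24, energy = 6),
    list(name = "ARC2", start_deg = 180, span_deg = 360, direction = "CW",
         speed_dps = 4.8, field_mm = c(240, 240), collimator_deg = 10,
         n_ctrl = 24, energy = 6))
  d <- withr::local_tempdir()
  files <- write_fixture_suite(spec, d)
  plan <- read_plan(files$rtplan)
  expect_equal(plan$isocenter, c(10, 0, 50))
  expect_length(plan$beams, 2)
  for (b in plan$beams) {
    w <- vapply(b$control_points, `[[`, numeric(1), "cum_weight")
    expect_false(is.unsorted(w))
    expect_equal(beam_arc_span(b), 360)
    expect_equal(nrow(b$control_points[[1]]$mlc) , 2)
    expect_equal(ncol(b$control_points[[1]]$mlc) + 1, length(b$leaf_boundaries))
  }
  expect_equal(plan$beams[[2]]$collimator_deg, 10)
})

test_that("fixture writing is deterministic for a fixed seed", {
  spec <- bb_fixture(seed = 42)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- write_fixture_suite(spec, d1)
  f2 <- write_fixture_suite(spec, d2)
  for (pair in list(c(f1$ct[1], f2$ct[1]), c(f1$rtstruct, f2$rtstruct),
                    c(f1$rtplan, f2$rtplan))) {
    b1 <- readBin(pair[1], "raw", file.info(pair[1])$size)
    b2 <- readBin(pair[2], "raw", file.info(pair[2])$size)
    expect_identical(b1, b2)
  }
})

test_that("BB validation fixture places the sphere at the documented offset", {
  cfg <- sim_preset("bb-validation", speed_dps = 1.5, seed = 3)
  d <- withr::local_tempdir()
  fx <- sim_fixture_suite(cfg, d)
  ct <- read_ct_geometry(fx$ct)
  ss <- read_structure_set(fx$rtstruct, ct)
  pl <- read_plan(fx$rtplan)
  # contour bounding-box center, patient mm, relative to the plan isocenter
  allpts <- do.call(rbind, ss$BB$contours)
  ctr <- (apply(allpts, 2, max) + apply(allpts, 2, min)) / 2
  rel <- ctr - pl$isocenter
  expect_equal(rel[1], -100, tolerance = 0.5)   # 10 cm lateral
  expect_equal(rel[3], -50, tolerance = 0.5)    # 5 cm longitudinal
  # and in room coordinates
  room <- patient_to_room(ctr, pl$isocenter)
  expect_equal(unname(room), c(-10, -5, 0), tolerance = 0.05)
})

test_that("written fixtures parse with an independent DICOM implementation", {
  py <- Sys.which("python")
  expect_true(nzchar(py))
  spec <- bb_fixture(seed = 13)
  d <- withr::local_tempdir()
  files <- write_fixture_suite(spec, d)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, json, pydicom",
    "ct = pydicom.dcmread(sys.argv[1])",
    "rs = pydicom.dcmread(sys.argv[2])",
    "rp = pydicom.dcmread(sys.argv[3])",
    "cp0 = rp.BeamSequence[0].ControlPointSequence[0]",
    "print(json.dumps({",
    " 'rows': int(ct.Rows), 'spacing': [float(v) for v in ct.PixelSpacing],",
    " 'roi': rs.StructureSetROISequence[0].ROIName,",
    " 'ncont': len(rs.ROIContourSequence[0].ContourSequence),",
    " 'iso': [float(v) for v in cp0.IsocenterPosition],",
    " 'gantry': float(cp0.GantryAngle)}))"), script)
  out <- system2(py, c(script, files$ct[1], files$rtstruct, files$rtplan),
                 stdout = TRUE)
  res <- jsonlite::fromJSON(out[length(out)])
  expect_equal(res$rows, spec$ct$dims[1])
  expect_equal(res$spacing, spec$ct$spacing[1:2])
  expect_equal(res$roi, "BB")
  expect_gte(res$ncont, 2)
  expect_equal(res$iso, spec$isocenter)
  expect_equal(res$gantry, 180)
})

test_that("malformed structure inputs are rejected with clear errors", {
  spec <- bb_fixture()
  spec$rois[[1]]$center <- c(-100, 0, 40)  # outside the z extent
  expect_error(write_fixture_suite(spec, tempfile()), "outside the CT grid")
})
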