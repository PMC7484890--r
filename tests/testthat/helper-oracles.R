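# Independent brute-force oracles and shared fixtures. The oracles
# deliberately use naive scalar loops, separate from the vectorized
# implementation paths they check.

# closed-form lateral projection for a point (Ox, 0, 0)
oracle_u_lateral <- function(ox, theta_deg, sad = 100) {
  th <- theta_deg * pi / 180
  sad * ox * cos(th) / (sad - ox * sin(th))
}

# scalar-loop even-odd point-in-polygon (crossing test), boundary-inclusive
oracle_pip <- function(px, py, poly, eps = 1e-9) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    x1 <- poly[j, 1]; y1 <- poly[j, 2]; x2 <- poly[i, 1]; y2 <- poly[i, 2]
    dx <- x2 - x1; dy <- y2 - y1
    L2 <- dx^2 + dy^2
    t <- if (L2 > 0) min(max(((px - x1) * dx + (py - y1) * dy) / L2, 0), 1) else 0
    if ((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2 <= eps^2) return(TRUE)
    if ((y1 > py) != (y2 > py)) {
      xint <- x1 + (py - y1) * dx / dy
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# scalar-loop first-hit ray cast per the plane-crossing rule: for one binned
# pixel, loop over every occupied lattice plane, intersect, round
# half-away-from-zero, test occupancy
oracle_raycast_pixel <- function(col0, row0, grid, theta_deg, isocenter_mm,
                                 geom) {
  th <- (theta_deg %% 360) * pi / 180
  sad <- geom$sad_cm
  s <- c(sad * sin(th), 0, sad * cos(th))
  nb <- geom$panel_matrix / 2
  ctr <- (nb - 1) / 2
  pitch_cm <- 2 * geom$pixel_iso_mm / 10
  u <- (col0 - ctr) * pitch_cm; v <- (row0 - ctr) * pitch_cm
  p_iso <- c(u * cos(th), v, -u * sin(th))
  d <- p_iso - s
  ct <- grid$ct; sp <- ct$spacing; occ <- grid$occ
  w <- which(occ, arr.ind = TRUE)
  if (nrow(w) == 0) return(FALSE)
  room_x <- function(j) (ct$origin[1] + (j - 1) * sp[2] - isocenter_mm[1]) / 10
  room_y <- function(k) (ct$origin[3] + (k - 1) * sp[3] - isocenter_mm[3]) / 10
  room_z <- function(i) -(ct$origin[2] + (i - 1) * sp[1] - isocenter_mm[2]) / 10
  to_idx <- function(x, y, z) {
    fj <- (x * 10 + isocenter_mm[1] - ct$origin[1]) / sp[2] + 1
    fi <- (-z * 10 + isocenter_mm[2] - ct$origin[2]) / sp[1] + 1
    fk <- (y * 10 + isocenter_mm[3] - ct$origin[3]) / sp[3] + 1
    r <- function(x) sign(x) * floor(abs(x) + 0.5)
    c(r(fi), r(fj), r(fk))
  }
  check <- function(tt) {
    if (!is.finite(tt) || tt < 0 || tt > geom$mag) return(FALSE)
    p <- s + tt * d
    ix <- to_idx(p[1], p[2], p[3])
    all(ix >= 1) && ix[1] <= dim(occ)[1] && ix[2] <= dim(occ)[2] &&
      ix[3] <= dim(occ)[3] && occ[ix[1], ix[2], ix[3]]
  }
  for (j in sort(unique(w[, 2])))
    if (abs(d[1]) > 1e-12 && check((room_x(j) - s[1]) / d[1])) return(TRUE)
  for (k in sort(unique(w[, 3])))
    if (abs(d[2]) > 1e-12 && check((room_y(k) - s[2]) / d[2])) return(TRUE)
  for (i in sort(unique(w[, 1])))
    if (abs(d[3]) > 1e-12 && check((room_z(i) - s[3]) / d[3])) return(TRUE)
  FALSE
}

# brute-force 8-neighbor boundary scan
oracle_boundary <- function(px) {
  n <- nrow(px); m <- ncol(px)
  out <- matrix(FALSE, n, m)
  for (r in seq_len(n)) for (c in seq_len(m)) {
    if (!px[r, c]) next
    if (r == 1 || r == n || c == 1 || c == m) { out[r, c] <- TRUE; next }
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      if (!px[r + dr, c + dc]) out[r, c] <- TRUE
    }
  }
  out
}

# brute-force 3x3 median with edge replication
oracle_median3x3 <- function(img) {
  n <- nrow(img); m <- ncol(img)
  out <- img
  for (r in seq_len(n)) for (c in seq_len(m)) {
    rr <- pmin(pmax((r - 1):(r + 1), 1), n)
    cc <- pmin(pmax((c - 1):(c + 1), 1), m)
    out[r, c] <- stats::median(as.vector(img[rr, cc]))
  }
  out
}

# ---- shared fixtures (built once per test run) -----------------------------

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small CT + sphere ROI fixture around a given patient-space center
bb_fixture <- function(center = c(-100, 0, 0), radius = 4, iso = c(0, 0, 50),
                       spacing = c(0.5, 0.5, 1.0), pad = c(12, 12, 9),
                       seed = 7) {
  dims <- ceiling(2 * pad / spacing)
  origin <- center - (dims[c(2, 1, 3)] - 1) / 2 * spacing[c(2, 1, 3)]
  list(
    ct = list(dims = dims, spacing = spacing, origin = origin),
    rois = list(list(name = "BB", color = c(255, 0, 0), shape = "sphere",
                     center = center, radius_mm = radius)),
    isocenter = iso,
    beams = list(list(name = "ARC1", start_deg = 180, span_deg = 360,
                      direction = "CW", speed_dps = 1.5,
                      field_mm = c(240, 240), collimator_deg = 0,
                      n_ctrl = 24, energy = 6)),
    seed = seed)
}

# the end-to-end BB validation projection set (720 angles), shared across
# test files
get_bb_projection_set <- function() {
  cache_get("bb_set", function() {
    d <- file.path(tempdir(), "cinemv_bb_fixture")
    cfg <- sim_preset("bb-validation", speed_dps = 1.5, seed = 1)
    fx <- sim_fixture_suite(cfg, d)
    ct <- read_ct_geometry(fx$ct)
    ss <- read_structure_set(fx$rtstruct, ct)
    pl <- read_plan(fx$rtplan)
    precompute_set(ss, pl, ct, linac_geometry())
  })
}

get_validation_report <- function(speed_dps, frame_stride, seed = 1) {
  key <- sprintf("val_%g_%d_%d", speed_dps, frame_stride, seed)
  cache_get(key, function() {
    cfg <- sim_preset("bb-validation", speed_dps = speed_dps, seed = seed)
    arc <- simulate_arc(cfg, frame_stride = frame_stride)
    evaluate_accuracy(arc, get_bb_projection_set(), sim_calibration(cfg),
                      NULL, "BB", linac_geometry())
  })
}
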