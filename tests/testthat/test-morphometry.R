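disk_fx <- analytic_contour("disk", r = 50)
disk_rg <- region_from_mask(disk_fx$mask)
square_fx <- analytic_contour("square", side = 100)
square_rg <- region_from_mask(square_fx$mask)
ell_fx <- analytic_contour("ellipse", a = 40, b = 20)
ell_rg <- region_from_mask(ell_fx$mask)
star_fx <- analytic_contour("star", r_outer = 50, r_inner = 20)
star_rg <- region_from_mask(star_fx$mask)

test_that("area and perimeter match analytic values", {
  g <- contour_geometry(disk_rg, 1)
  expect_equal(g$area, pi * 50^2, tolerance = 0.02)
  expect_equal(g$perimeter, 2 * pi * 50, tolerance = 0.03)
  gs <- contour_geometry(square_rg, 0.25)
  expect_equal(gs$area, 625)                 # 100x100 px at 0.25 um/px
  expect_equal(gs$perimeter, 100, tolerance = 0.03)
  # traced contour agrees with the arc-length oracle on the generating polygon
  expect_equal(polygon_perimeter(disk_rg$contour),
               oracle_polygon_perimeter(disk_fx$polygon), tolerance = 0.03)
})

test_that("equivalent ellipse recovers axes, isotropy, rotation invariance", {
  e <- equivalent_ellipse(ell_rg, 1)
  expect_equal(e$length, 80, tolerance = 0.02)
  expect_equal(e$width, 40, tolerance = 0.02)
  d <- equivalent_ellipse(disk_rg, 1)
  expect_lte(d$length / d$width, 1.02)
  rot <- region_from_mask(analytic_contour("ellipse", a = 40, b = 20,
                                           rotation = pi / 4)$mask)
  er <- equivalent_ellipse(rot, 1)
  expect_equal(er$length, e$length, tolerance = 0.02)
  expect_equal(er$width, e$width, tolerance = 0.02)
  # Feret mode: diameters of the convex hull
  f <- equivalent_ellipse(disk_rg, 1, mode = "feret")
  expect_equal(f$length, 100, tolerance = 0.03)
  expect_equal(f$width, 100, tolerance = 0.03)
})

test_that("aspect and roundness follow their closed forms", {
  expect_equal(aspect(80, 40), 2)
  expect_equal(aspect(14, 7), 2)          # the cohort-mean vessel, 14 x 7 um
  expect_error(aspect(10, 0), "> 0")
  expect_equal(roundness(2 * pi * 7, pi * 7^2), 1)       # circle, exactly
  expect_equal(roundness(4 * 3, 3^2), 4 / pi)            # square, exactly
  g <- contour_geometry(disk_rg, 1)
  expect_gte(roundness(g$perimeter, g$area), 0.98)
  expect_lte(roundness(g$perimeter, g$area), 1.06)
})

test_that("convex contour is idempotent and finds star tips", {
  hull <- convex_contour(disk_rg)
  rehull <- convex_polygon(hull)
  expect_equal(polygon_area(rehull), polygon_area(hull), tolerance = 1e-9)
  # hull of the exact star polygon is the 5 outer tips
  sp <- star_fx$polygon
  h <- convex_polygon(sp)
  expect_equal(nrow(h) - 1, 5)
  expect_gte(polygon_area(convex_contour(star_rg)),
             polygon_area(star_rg$contour))
  expect_error(convex_polygon(cbind(1:5, 1:5)), "collinear")
})

test_that("perimeter ratio and deformity quantify outline irregularity", {
  expect_equal(perimeter_ratio(disk_rg), 1, tolerance = 0.03)
  expect_lte(perimeter_ratio(disk_rg), 1 + 0.03)
  # exact polygon oracle for the 5-point star: hull perimeter / star perimeter
  sp <- star_fx$polygon
  oracle_ratio <- oracle_polygon_perimeter(convex_polygon(sp)) /
    oracle_polygon_perimeter(sp)
  expect_equal(perimeter_ratio(star_rg), oracle_ratio, tolerance = 0.05)
  expect_lt(perimeter_ratio(star_rg), 0.87)

  expect_lte(deformity(disk_rg, 1), 0.01 * disk_rg$area_px)
  # star deformity vs the shoelace oracle on hull and star polygons; the
  # 36-degree tips lose their outermost ~1.5 px to rasterization, so an 80 px
  # star is needed for the raster to track the polygon within 5%
  big <- analytic_contour("star", r_outer = 80, r_inner = 32)
  oracle_def <- oracle_polygon_area(convex_polygon(big$polygon)) -
    oracle_polygon_area(big$polygon)
  expect_equal(deformity(region_from_mask(big$mask), 1), oracle_def,
               tolerance = 0.05)
  for (rg in list(disk_rg, square_rg, ell_rg, star_rg))
    expect_gte(deformity(rg, 1), -0.01 * rg$area_px)
})

test_that("Hu invariants match theory and the brute-force oracle", {
  hu <- hu_log_moments(disk_rg)
  expect_equal(hu$h[1], 1 / (2 * pi), tolerance = 0.01)
  expect_gt(hu$h[1], 0)
  # brute-force double-sum oracle on the star raster
  expect_equal(hu$h, oracle_hu(disk_fx$mask), tolerance = 1e-9)
  hs <- hu_log_moments(star_rg)
  expect_equal(hs$h, oracle_hu(star_fx$mask), tolerance = 1e-9)
})

test_that("Hu log moments are translation/rotation invariant, h7 mirror-odd", {
  # an asymmetric blob, so the third-order invariants are genuinely nonzero
  # (for symmetric shapes like the star they vanish in the continuum and
  # their rasterized values are pure discretization noise)
  blob <- function(rot, nr = 200, nc = 220, ctr = c(90, 100)) {
    th <- seq(0, 2 * pi, length.out = 721)
    r <- 55 * (1 + 0.25 * cos(th - rot) + 0.15 * sin(2 * (th - rot)))
    poly <- cbind(ctr[1] + r * sin(th), ctr[2] + r * cos(th))
    region_from_mask(vesselmorph:::rasterize_polygon(poly, nr, nc))
  }
  b0 <- hu_log_moments(blob(0))
  meaningful <- which(!is.na(b0$m) & abs(b0$h) >= 1e-6)
  expect_gte(length(meaningful), 3)
  # translation: same blob at a different position
  sh <- hu_log_moments(blob(0, ctr = c(105, 115)))
  rot <- hu_log_moments(blob(0.7))
  for (i in meaningful) {
    expect_equal(sh$m[i], b0$m[i], tolerance = 1e-3)
    expect_equal(rot$m[i], b0$m[i], tolerance = 1e-2)
  }
  # mirror image: h7 flips sign, h1..h6 unchanged
  bm <- blob(0)
  mir_mask <- matrix(FALSE, 200, 220)
  mir_mask[cbind(bm$pixels[, 1], 221L - bm$pixels[, 2])] <- TRUE
  hm <- hu_log_moments(region_from_mask(mir_mask))$h
  h0 <- hu_log_moments(bm)$h
  for (i in 1:6)
    if (abs(h0[i]) >= 1e-6)
      expect_equal(hm[i], h0[i], tolerance = 1e-6)
  expect_equal(hm[7], -h0[7], tolerance = 1e-6)
})

test_that("shape factor separates convex from star-shaped vessels", {
  sf_disk <- shape_factor(disk_rg)
  expect_lte(sf_disk, 0.05)
  expect_gt(shape_factor(star_rg), sf_disk)
  # restricting the index set is supported
  expect_gte(shape_factor(star_rg, index_set = 1:2), 0)
})

test_that("branch counting distinguishes bars, Y- and plus-shaped tubes", {
  bar <- matrix(FALSE, 40, 240); bar[15:24, 21:220] <- TRUE
  expect_equal(branch_count(bar), 0)
  n <- 301
  X <- matrix(rep(1:n, each = n), n, n); Y <- matrix(rep(1:n, times = n), n, n)
  segd <- function(ang, len) {
    u <- cos(ang) * (X - 151) + sin(ang) * (Y - 151)
    v <- -sin(ang) * (X - 151) + cos(ang) * (Y - 151)
    t <- pmin(pmax(u, 0), len)
    sqrt((u - t)^2 + v^2)
  }
  ytube <- pmin(segd(pi / 2, 100),
                pmin(segd(pi / 2 + 2 * pi / 3, 100),
                     segd(pi / 2 + 4 * pi / 3, 100))) <= 5
  expect_equal(branch_count(ytube), 1)
  plus <- pmin(pmin(segd(0, 100), segd(pi / 2, 100)),
               pmin(segd(pi, 100), segd(3 * pi / 2, 100))) <= 5
  expect_equal(branch_count(plus), 1)
  expect_equal(branch_count(disk_rg), 0)
})

test_that("measure_vessel assembles a consistent record", {
  m <- measure_vessel(disk_rg, 1)
  expect_equal(m$aspect, 1, tolerance = 0.02)
  expect_equal(m$roundness, 1, tolerance = 0.06)
  expect_equal(m$perimeter_ratio, 1, tolerance = 0.03)
  expect_lte(m$deformity_um2, 0.01 * m$area_um2)
  expect_lte(m$shape_factor, 0.05)
  expect_equal(m$branch_count, 0)
  me <- measure_vessel(ell_rg, 1)
  expect_equal(me$aspect, 2, tolerance = 0.04)
  ms <- measure_vessel(star_rg, 1)
  for (f in c("roundness", "deformity_um2", "shape_factor"))
    expect_gt(ms[[f]], m[[f]])
  expect_lt(ms$perimeter_ratio, m$perimeter_ratio)
})

test_that("descriptors scale correctly with pixel calibration", {
  m1 <- measure_vessel(ell_rg, 0.5)
  m2 <- measure_vessel(ell_rg, 1.0)
  expect_equal(m2$length_um, 2 * m1$length_um)
  expect_equal(m2$width_um, 2 * m1$width_um)
  expect_equal(m2$perimeter_um, 2 * m1$perimeter_um)
  expect_equal(m2$area_um2, 4 * m1$area_um2)
  expect_equal(m2$deformity_um2, 4 * m1$deformity_um2)
  for (f in c("aspect", "roundness", "perimeter_ratio", "shape_factor",
              "branch_count"))
    expect_identical(m1[[f]], m2[[f]])
})
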