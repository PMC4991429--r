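# Per-vessel morphometric descriptors.
#
# Size descriptors (area, length, width, perimeter) are reported in physical
# units; shape descriptors (aspect, roundness, perimeter ratio normalised
# forms, shape factor) are dimensionless and therefore independent of the
# pixel scale; deformity is an area and scales with mpp^2.

#' Area and perimeter of a vessel region
#'
#' Area is the filled pixel count times `mpp^2`; perimeter is the Euclidean
#' arc length of the traced sub-pixel outer contour times `mpp`.
#'
#' @param region a `vessel_region`.
#' @param microns_per_pixel calibration (um/px).
#' @return Named list `area` (um^2) and `perimeter` (um).
#' @export
contour_geometry <- function(region, microns_per_pixel) {
  stopifnot(inherits(region, "vessel_region"), microns_per_pixel > 0)
  if (region$area_px < 1) stop("empty region")
  list(area = region$area_px * microns_per_pixel^2,
       perimeter = polygon_perimeter(region$contour) * microns_per_pixel)
}

# second central moments of a pixel set (point masses at pixel centers)
pixel_central_moments <- function(pixels) {
  r <- pixels[, 1]; cc <- pixels[, 2]
  n <- length(r)
  rc <- r - mean(r); cg <- cc - mean(cc)
  list(n = n, mu20 = sum(rc^2), mu02 = sum(cg^2), mu11 = sum(rc * cg))
}

#' Equivalent-ellipse axes of a vessel region
#'
#' Full major/minor axis lengths of the ellipse with the same second central
#' moments as the filled region. With `mode = "feret"` the maximal and
#' minimal Feret diameters of the convex hull are returned instead.
#'
#' @param region a `vessel_region`.
#' @param microns_per_pixel calibration (um/px).
#' @param mode `"ellipse"` (default) or `"feret"`.
#' @return Named list `length` (um, major), `width` (um, minor),
#'   `orientation` (radians, major-axis direction). A degenerate (collinear)
#'   region gets a width floor of one pixel.
#' @export
equivalent_ellipse <- function(region, microns_per_pixel,
                               mode = c("ellipse", "feret")) {
  mode <- match.arg(mode)
  stopifnot(inherits(region, "vessel_region"), microns_per_pixel > 0)
  if (mode == "feret") {
    f <- feret_diameters(region$contour)
    return(list(length = f[1] * microns_per_pixel,
                width = max(f[2], 1) * microns_per_pixel,
                orientation = f[3]))
  }
  m <- pixel_central_moments(region$pixels)
  cv <- matrix(c(m$mu20, m$mu11, m$mu11, m$mu02), 2, 2) / m$n
  eg <- eigen(cv, symmetric = TRUE)
  ax <- 4 * sqrt(pmax(eg$values, 0))
  list(length = max(ax[1], 1) * microns_per_pixel,
       width = max(ax[2], 1) * microns_per_pixel,
       orientation = atan2(eg$vectors[2, 1], eg$vectors[1, 1]))
}

# (max Feret, min Feret, orientation of max) of a closed polygon, via hull
# vertex pairs / edge projections
feret_diameters <- function(contour) {
  hull <- convex_polygon(contour)[-1, , drop = FALSE]
  n <- nrow(hull)
  dmax <- 0; ang <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d2 <- sum((hull[i, ] - hull[j, ])^2)
    if (d2 > dmax) { dmax <- d2; ang <- atan2(hull[j, 2] - hull[i, 2],
                                              hull[j, 1] - hull[i, 1]) }
  }
  wmin <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2)); if (len == 0) next
    nvec <- c(-e[2], e[1]) / len
    proj <- as.vector(hull %*% nvec)
    wmin <- min(wmin, max(proj) - min(proj))
  }
  c(sqrt(dmax), wmin, ang)
}

#' Aspect ratio
#'
#' Major axis / minor axis of the equivalent ellipse; >= 1 by construction
#' (1 = round, larger = ovoid/elongated).
#'
#' @param length major axis (um).
#' @param width minor axis (um), > 0.
#' @return Dimensionless ratio.
#' @export
aspect <- function(length, width) {
  if (any(width <= 0)) stop("width must be > 0")
  length / width
}

#' Roundness
#'
#' `perimeter^2 / (4 * pi * area)`: 1 for a perfect circle, growing with
#' boundary protrusions (4/pi for a square).
#'
#' @param perimeter contour perimeter (um).
#' @param area region area (um^2), > 0.
#' @return Dimensionless, ~>= 1.
#' @export
roundness <- function(perimeter, area) {
  if (any(area <= 0)) stop("area must be > 0")
  perimeter^2 / (4 * pi * area)
}

#' Convex contour of a vessel region
#'
#' Convex hull of the traced outer contour vertices, the "polygon best
#' fitting" reference shape for perimeter ratio, deformity and shape factor.
#'
#' @param region a `vessel_region`.
#' @return Closed convex polygon (counter-clockwise, first vertex repeated).
#' @export
convex_contour <- function(region) {
  stopifnot(inherits(region, "vessel_region"))
  convex_polygon(region$contour)
}

#' Perimeter ratio
#'
#' Convex contour perimeter / contour perimeter: ~1 for convex outlines,
#' < 1 for irregular ones (the hull is the shortest enclosing convex curve).
#'
#' @param region a `vessel_region`.
#' @return Dimensionless value in (0, 1 + epsilon].
#' @export
perimeter_ratio <- function(region) {
  polygon_perimeter(convex_contour(region)) /
    polygon_perimeter(region$contour)
}

#' Deformity
#'
#' Convex contour area minus region area, in um^2: 0 for convex vessels,
#' large for strongly deformed ones.
#'
#' @param region a `vessel_region`.
#' @param microns_per_pixel calibration (um/px).
#' @return Area deficit (um^2), >= 0 up to rasterization error.
#' @export
deformity <- function(region, microns_per_pixel) {
  stopifnot(microns_per_pixel > 0)
  (polygon_area(convex_contour(region)) - region$area_px) *
    microns_per_pixel^2
}

# raw moment M_pq = sum r^p c^q over pixel centers
region_hu <- function(pixels) {
  hu_from_moments(pixel_raw_moments(pixels))
}

pixel_raw_moments <- function(pixels) {
  r <- pixels[, 1]; cc <- pixels[, 2]
  list(m00 = length(r), m10 = sum(r), m01 = sum(cc),
       m20 = sum(r^2), m02 = sum(cc^2), m11 = sum(r * cc),
       m30 = sum(r^3), m03 = sum(cc^3),
       m21 = sum(r^2 * cc), m12 = sum(r * cc^2))
}

# Hu's seven invariants from raw moments (any consistent 2-D coordinate pair)
hu_from_moments <- function(m) {
  xb <- m$m10 / m$m00; yb <- m$m01 / m$m00
  mu20 <- m$m20 - xb * m$m10
  mu02 <- m$m02 - yb * m$m01
  mu11 <- m$m11 - xb * m$m01
  mu30 <- m$m30 - 3 * xb * m$m20 + 2 * xb^2 * m$m10
  mu03 <- m$m03 - 3 * yb * m$m02 + 2 * yb^2 * m$m01
  mu21 <- m$m21 - 2 * xb * m$m11 - yb * m$m20 + 2 * xb^2 * m$m01
  mu12 <- m$m12 - 2 * yb * m$m11 - xb * m$m02 + 2 * yb^2 * m$m10
  n <- function(mu, p, q) mu / m$m00^(1 + (p + q) / 2)
  e20 <- n(mu20, 2, 0); e02 <- n(mu02, 0, 2); e11 <- n(mu11, 1, 1)
  e30 <- n(mu30, 3, 0); e03 <- n(mu03, 0, 3)
  e21 <- n(mu21, 2, 1); e12 <- n(mu12, 1, 2)
  h1 <- e20 + e02
  h2 <- (e20 - e02)^2 + 4 * e11^2
  h3 <- (e30 - 3 * e12)^2 + (3 * e21 - e03)^2
  h4 <- (e30 + e12)^2 + (e21 + e03)^2
  h5 <- (e30 - 3 * e12) * (e30 + e12) *
          ((e30 + e12)^2 - 3 * (e21 + e03)^2) +
        (3 * e21 - e03) * (e21 + e03) *
          (3 * (e30 + e12)^2 - (e21 + e03)^2)
  h6 <- (e20 - e02) * ((e30 + e12)^2 - (e21 + e03)^2) +
        4 * e11 * (e30 + e12) * (e21 + e03)
  h7 <- (3 * e21 - e03) * (e30 + e12) *
          ((e30 + e12)^2 - 3 * (e21 + e03)^2) -
        (e30 - 3 * e12) * (e21 + e03) *
          (3 * (e30 + e12)^2 - (e21 + e03)^2)
  c(h1, h2, h3, h4, h5, h6, h7)
}

#' Hu invariant moments with log scaling
#'
#' Computes the seven Hu invariants `h1..h7` of the filled region (point
#' masses at pixel centers) and the log-scaled values
#' `m_i = sign(h_i) * log10(|h_i|)`. Invariants with `|h_i| < 1e-30` are
#' flagged undefined (`m_i = NA`).
#'
#' @param x a `vessel_region` or an n x 2 pixel coordinate matrix.
#' @return Object of class `hu_signature`: list with numeric `h` and `m`
#'   (length 7 each).
#' @export
hu_log_moments <- function(x) {
  pixels <- if (inherits(x, "vessel_region")) x$pixels else x
  if (is.null(dim(pixels)) || nrow(pixels) < 1) stop("zero-area input")
  h <- region_hu(pixels)
  m <- ifelse(abs(h) < 1e-30, NA_real_, sign(h) * log10(abs(h)))
  structure(list(h = h, m = m), class = "hu_signature")
}

#' @export
print.hu_signature <- function(x, ...) {
  cat("<hu_signature>\n")
  print(rbind(h = signif(x$h, 4), m = signif(x$m, 4)))
  invisible(x)
}

#' Hu-moment shape factor
#'
#' Compares the Hu log-moment signature of the filled region (A) with that of
#' its filled convex contour (B):
#' `max_i |m_i^A - m_i^B| / |m_i^A|` over the chosen index set, skipping
#' indices where `m_i^A` is undefined or ~0. Near 0 when the vessel matches
#' its convex contour, growing with concavities.
#'
#' Invariants smaller than `min_h` are skipped as well: for symmetric shapes
#' the higher Hu invariants vanish in the continuum, so their rasterized
#' values are pure discretization noise and their log ratios would swing
#' arbitrarily with pixel alignment.
#'
#' @param region a `vessel_region`.
#' @param index_set Hu indices to compare (default all seven).
#' @param min_h noise floor: indices with `|h_i|` below this in either shape
#'   are skipped.
#' @return Dimensionless, >= 0.
#' @export
shape_factor <- function(region, index_set = 1:7, min_h = 1e-6) {
  stopifnot(inherits(region, "vessel_region"), all(index_set %in% 1:7))
  a <- hu_log_moments(region)
  hull <- convex_contour(region)
  hpix <- which(rasterize_convex(hull, region$dim[1], region$dim[2]),
                arr.ind = TRUE)
  b <- hu_log_moments(hpix)
  usable <- index_set[!is.na(a$m[index_set]) & !is.na(b$m[index_set]) &
                      abs(a$h[index_set]) >= min_h &
                      abs(b$h[index_set]) >= min_h &
                      abs(a$m[index_set]) >= 1e-12]
  if (!length(usable)) stop("no usable Hu index (all undefined)")
  max(abs(a$m[usable] - b$m[usable]) / abs(a$m[usable]))
}

#' Measure the full descriptor suite of one vessel
#'
#' @param region a `vessel_region`.
#' @param microns_per_pixel calibration (um/px).
#' @param hu_index_set Hu indices for the shape factor.
#' @param axis_mode `"ellipse"` or `"feret"` length/width definition.
#' @return One-row `data.frame` (class `vessel_morphometry`) with columns
#'   `area_um2`, `length_um`, `width_um`, `perimeter_um`, `aspect`,
#'   `roundness`, `perimeter_ratio`, `deformity_um2`, `shape_factor`,
#'   `branch_count`, `touches_border`.
#' @export
measure_vessel <- function(region, microns_per_pixel, hu_index_set = 1:7,
                           axis_mode = "ellipse") {
  g <- contour_geometry(region, microns_per_pixel)
  e <- equivalent_ellipse(region, microns_per_pixel, axis_mode)
  out <- data.frame(
    area_um2 = g$area,
    length_um = e$length,
    width_um = e$width,
    perimeter_um = g$perimeter,
    aspect = aspect(e$length, e$width),
    roundness = roundness(g$perimeter, g$area),
    perimeter_ratio = perimeter_ratio(region),
    deformity_um2 = deformity(region, microns_per_pixel),
    shape_factor = shape_factor(region, hu_index_set),
    branch_count = branch_count(region),
    touches_border = region$touches_border)
  class(out) <- c("vessel_morphometry", class(out))
  out
}

#' Measure all regions of a tile
#'
#' @param regions list of `vessel_region` from [fill_and_label()].
#' @param microns_per_pixel calibration (um/px).
#' @param hu_index_set,axis_mode passed to [measure_vessel()].
#' @return `data.frame` with one row per region (a `label` column first);
#'   zero-row frame with the full schema if `regions` is empty.
#' @export
measure_regions <- function(regions, microns_per_pixel, hu_index_set = 1:7,
                            axis_mode = "ellipse") {
  if (!length(regions)) {
    out <- data.frame(label = integer(0), area_um2 = numeric(0),
                      length_um = numeric(0), width_um = numeric(0),
                      perimeter_um = numeric(0), aspect = numeric(0),
                      roundness = numeric(0), perimeter_ratio = numeric(0),
                      deformity_um2 = numeric(0), shape_factor = numeric(0),
                      branch_count = integer(0), touches_border = logical(0))
    return(out)
  }
  rows <- lapply(regions, function(rg)
    cbind(label = rg$label,
          measure_vessel(rg, microns_per_pixel, hu_index_set, axis_mode)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}
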