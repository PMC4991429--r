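# Synthetic phantom tiles with per-vessel ground truth.
#
# Every shape's scale is calibrated so that its target caliber_um equals the
# equivalent-ellipse minor axis of the rasterized filled shape. This keeps
# "caliber" consistent between the generator and the measurement pipeline for
# every morphology, including branched tubes (whose second moments are
# isotropic under 3-fold symmetry, so the minor axis tracks arm span, not
# tube width) and stars. Calibration uses exact polygon (Green's-theorem)
# moments where a polygon model exists, and a fixed-point iteration on the
# rasterized mask otherwise.

#' Specify one synthetic vessel
#'
#' @param shape one of `"ring"`, `"open_ring"`, `"ellipse_ring"`, `"tube"`,
#'   `"branched_tube"`, `"star_cistern"`.
#' @param center_um numeric(2), (x, y) position of the vessel center in um
#'   (x = column direction, y = row direction).
#' @param caliber_um target vessel width: the equivalent-ellipse minor axis
#'   of the filled (wall + lumen) shape.
#' @param length_um target major axis (um); used by `ellipse_ring` and
#'   `tube`, ignored (set to `caliber_um`) for isotropic shapes.
#' @param wall_thickness_um endothelial wall thickness (um).
#' @param gap_fraction fraction of the outline circumference left open
#'   (`open_ring` only; must be < 0.5).
#' @param rotation orientation (radians).
#' @param n_points star points (`star_cistern` only).
#' @param thresholds [segment_thresholds()] used to derive `true_class` from
#'   `caliber_um`.
#' @return An object of class `vessel_spec` with the derived `true_class`.
#' @export
vessel_spec <- function(shape = c("ring", "open_ring", "ellipse_ring", "tube",
                                  "branched_tube", "star_cistern"),
                        center_um, caliber_um, length_um = NULL,
                        wall_thickness_um = 2.5, gap_fraction = 0,
                        rotation = 0, n_points = 5,
                        thresholds = segment_thresholds()) {
  shape <- match.arg(shape)
  stopifnot(length(center_um) == 2, caliber_um > 0,
            gap_fraction >= 0, gap_fraction < 0.5, wall_thickness_um > 0)
  if (caliber_um < thresholds$min_width)
    stop("caliber_um below min_width")
  if (is.null(length_um) || shape %in% c("ring", "open_ring",
                                         "branched_tube", "star_cistern"))
    length_um <- caliber_um
  if (length_um < caliber_um) stop("length_um must be >= caliber_um")
  structure(list(shape = shape, center_um = as.numeric(center_um),
                 caliber_um = caliber_um, length_um = length_um,
                 wall_thickness_um = wall_thickness_um,
                 gap_fraction = gap_fraction, rotation = rotation,
                 n_points = as.integer(n_points),
                 true_class = as.character(classify_vessel(caliber_um,
                                                           thresholds))),
            class = "vessel_spec")
}

# closed polygon of a capsule (stadium): half-length hl, cap radius R,
# centered at origin, axis along x
capsule_polygon <- function(R, hl, npts = 60) {
  th1 <- seq(-pi / 2, pi / 2, length.out = npts)      # right cap
  th2 <- seq(pi / 2, 3 * pi / 2, length.out = npts)   # left cap
  x <- c(hl + R * cos(th1), -hl + R * cos(th2))
  y <- c(R * sin(th1), R * sin(th2))
  cbind(c(x, x[1]), c(y, y[1]))
}

# closed star polygon, outer radius Ro, inner radius ri, n points
star_polygon <- function(Ro, ri, n = 5, rotation = 0) {
  k <- seq_len(2 * n)
  ang <- rotation + (k - 1) * pi / n - pi / 2
  rad <- ifelse(k %% 2 == 1, Ro, ri)
  v <- cbind(rad * cos(ang), rad * sin(ang))
  rbind(v, v[1, , drop = FALSE])
}

# resolved pixel-space geometry of a spec: list with px-unit parameters and
# the enclosing radius (px) used for overlap/fit checks
resolve_geometry <- function(spec, mpp) {
  cal <- spec$caliber_um / mpp
  len <- spec$length_um / mpp
  w <- spec$wall_thickness_um / mpp
  g <- list(shape = spec$shape, cx = spec$center_um[1] / mpp,
            cy = spec$center_um[2] / mpp, w = w, rot = spec$rotation,
            gap = spec$gap_fraction, n_points = spec$n_points)
  if (spec$shape %in% c("ring", "open_ring")) {
    g$R <- cal / 2
    g$enclosing <- g$R
  } else if (spec$shape == "ellipse_ring") {
    g$a <- len / 2; g$b <- cal / 2
    g$enclosing <- g$a
  } else if (spec$shape == "tube") {
    R <- cal / 2 / 1.1547; hl <- max(len / 2 - R, 1)
    for (i in 1:5) {
      ax <- polygon_ellipse_axes(capsule_polygon(R, hl))
      R <- R * cal / ax[2]
      hl <- max(hl * len / ax[1], 0.5)
    }
    g$R <- R; g$hl <- hl
    g$enclosing <- hl + R
  } else if (spec$shape == "branched_tube") {
    g$tr <- 0.2 * cal                     # arm tube radius (px)
    arm <- cal / 1.633                    # 3-fold symmetry: minor ~ 1.633 arm
    for (i in 1:3) {
      mk <- branched_mask_local(arm, g$tr, g$rot)
      px <- which(mk, arr.ind = TRUE)
      m <- pixel_central_moments(px)
      minor <- 4 * sqrt(min(eigen(matrix(c(m$mu20, m$mu11, m$mu11, m$mu02),
                                         2, 2) / m$n,
                                  symmetric = TRUE,
                                  only.values = TRUE)$values))
      arm <- arm * cal / minor
    }
    g$arm <- arm
    g$enclosing <- arm + g$tr
  } else if (spec$shape == "star_cistern") {
    inner_ratio <- 0.45
    unit <- star_polygon(1, inner_ratio, spec$n_points, spec$rotation)
    minor_unit <- polygon_ellipse_axes(unit)[2]
    g$Ro <- cal / minor_unit
    g$ri <- inner_ratio * g$Ro
    g$enclosing <- g$Ro
  }
  g
}

# arm directions of a branched (Y) tube
branch_angles <- function(rot) rot + c(0, 2, 4) * pi / 3 + pi / 2

# local raster of a Y tube for calibration (own small grid)
branched_mask_local <- function(arm, tr, rot) {
  ext <- ceiling(arm + tr) + 2
  n <- 2 * ext + 1
  X <- matrix(rep(seq_len(n) - ext - 1, each = n), n, n)   # col offsets
  Y <- matrix(rep(seq_len(n) - ext - 1, times = n), n, n)  # row offsets
  d <- branched_distance(X, Y, arm, rot)
  d <= tr
}

# distance from (X, Y) offsets to the 3-arm segment set
branched_distance <- function(X, Y, arm, rot) {
  d <- NULL
  for (ang in branch_angles(rot)) {
    u <- cos(ang) * X + sin(ang) * Y
    v <- -sin(ang) * X + cos(ang) * Y
    t <- pmin(pmax(u, 0), arm)
    dk <- sqrt((u - t)^2 + v^2)
    d <- if (is.null(d)) dk else pmin(d, dk)
  }
  d
}

# filled and wall masks of one resolved spec over pixel grids X (col coords)
# and Y (row coords)
shape_masks <- function(g, X, Y) {
  dx <- X - g$cx; dy <- Y - g$cy
  if (g$shape %in% c("ring", "open_ring")) {
    d <- sqrt(dx^2 + dy^2)
    filled <- d <= g$R
    wall <- filled & d > g$R - g$w
    if (g$shape == "open_ring" && g$gap > 0) {
      th <- atan2(dy, dx) - g$rot
      th <- atan2(sin(th), cos(th))              # wrap to (-pi, pi]
      wall <- wall & !(abs(th) <= g$gap * pi)
    }
  } else if (g$shape == "ellipse_ring") {
    u <- cos(g$rot) * dx + sin(g$rot) * dy
    v <- -sin(g$rot) * dx + cos(g$rot) * dy
    filled <- (u / g$a)^2 + (v / g$b)^2 <= 1
    ai <- max(g$a - g$w, 0.5); bi <- max(g$b - g$w, 0.5)
    wall <- filled & (u / ai)^2 + (v / bi)^2 > 1
  } else if (g$shape == "tube") {
    u <- cos(g$rot) * dx + sin(g$rot) * dy
    v <- -sin(g$rot) * dx + cos(g$rot) * dy
    t <- pmin(pmax(u, -g$hl), g$hl)
    d <- sqrt((u - t)^2 + v^2)
    filled <- d <= g$R
    wall <- filled & d > g$R - g$w
  } else if (g$shape == "branched_tube") {
    d <- branched_distance(dx, dy, g$arm, g$rot)
    filled <- d <= g$tr
    wall <- filled & d > g$tr - g$w
  } else {  # star_cistern
    nr <- nrow(X); nc <- ncol(X)
    outer <- star_polygon(g$Ro, g$ri, g$n_points, g$rot)
    shrink <- max(0.3, 1 - 2 * g$w / (g$Ro + g$ri))
    # polygons are (x, y); raster grid is (row, col) = (y, x)
    po <- cbind(outer[, 2] + g$cy, outer[, 1] + g$cx)
    pi_ <- cbind(outer[, 2] * shrink + g$cy, outer[, 1] * shrink + g$cx)
    filled <- rasterize_polygon(po, nr, nc)
    wall <- filled & !rasterize_polygon(pi_, nr, nc)
  }
  list(filled = filled, wall = wall)
}

#' Render a synthetic IHC phantom tile
#'
#' Paints DAB-brown vessel walls (optical density `vessel_dab_od` along the
#' DAB stain vector) on a hematoxylin-tinted tissue background (OD
#' `tissue_od` along the hematoxylin vector), with an optional white
#' (non-tissue) margin, then adds i.i.d. Gaussian pixel noise. Colours are
#' produced by inverting the optical-density transform
#' `OD = -log10((I + 1) / 256)`.
#'
#' @param specs list of [vessel_spec()] objects.
#' @param tile_size_um numeric(2), tile (height, width) in um.
#' @param microns_per_pixel calibration (um/px).
#' @param noise_sd Gaussian noise standard deviation on the `[0, 1]`
#'   intensity scale (default 4/255).
#' @param seed integer seed fixing all randomness; the caller's RNG state is
#'   restored on exit.
#' @param white_margin_um width of the white non-tissue border band (um).
#' @param tissue_od,vessel_dab_od background and wall optical densities.
#' @param min_gap_um minimum allowed gap between vessel enclosing circles;
#'   violations are an error naming the offending pair.
#' @param stain [stain_config()] providing the stain vectors.
#' @param sample_id label for the generated tile.
#' @return List with `tile` (an [image_tile()]) and `truth` (class
#'   `phantom_truth`): `specs`, `tissue_fraction`, `stained_pixel_count`,
#'   `wall_mask`, `filled_labels` (ground-truth label matrix) and `vessels`
#'   (per-vessel `data.frame`: id, shape, `true_class`, center, caliber,
#'   filled/wall pixel counts, area and the measured equivalent-ellipse axes
#'   of the rasterized filled shape).
#' @export
render_phantom_tile <- function(specs, tile_size_um = c(500, 500),
                                microns_per_pixel = 0.5, noise_sd = 4 / 255,
                                seed = 1L, white_margin_um = 0,
                                tissue_od = 0.15, vessel_dab_od = 0.9,
                                min_gap_um = 10, stain = stain_config(),
                                sample_id = "phantom") {
  stopifnot(length(tile_size_um) == 2, microns_per_pixel > 0, noise_sd >= 0)
  if (inherits(specs, "vessel_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "vessel_spec")))
  mpp <- microns_per_pixel
  nr <- round(tile_size_um[1] / mpp); nc <- round(tile_size_um[2] / mpp)
  geoms <- lapply(specs, resolve_geometry, mpp = mpp)
  margin_px <- white_margin_um / mpp

  # fit and overlap checks on enclosing circles
  for (i in seq_along(geoms)) {
    gi <- geoms[[i]]
    if (gi$cy - gi$enclosing < margin_px + 1 ||
        gi$cy + gi$enclosing > nr - margin_px ||
        gi$cx - gi$enclosing < margin_px + 1 ||
        gi$cx + gi$enclosing > nc - margin_px)
      stop("vessel ", i, " does not fit inside the tissue region")
  }
  if (length(geoms) > 1) {
    for (i in seq_len(length(geoms) - 1)) for (j in (i + 1):length(geoms)) {
      gi <- geoms[[i]]; gj <- geoms[[j]]
      gap <- sqrt((gi$cx - gj$cx)^2 + (gi$cy - gj$cy)^2) -
             gi$enclosing - gj$enclosing
      if (gap < min_gap_um / mpp)
        stop(sprintf("vessels %d and %d violate the minimum gap (%.1f < %.1f um)",
                     i, j, gap * mpp, min_gap_um))
    }
  }

  X <- matrix(rep(seq_len(nc), each = nr), nr, nc)   # col coordinate
  Y <- matrix(rep(seq_len(nr), times = nc), nr, nc)  # row coordinate
  tissue <- Y > margin_px & Y <= nr - margin_px &
            X > margin_px & X <= nc - margin_px

  wall_all <- matrix(FALSE, nr, nc)
  filled_labels <- matrix(0L, nr, nc)
  vrows <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    mk <- shape_masks(geoms[[i]], X, Y)
    wall_all <- wall_all | mk$wall
    filled_labels[mk$filled] <- i
    pxm <- which(mk$filled, arr.ind = TRUE)
    mom <- pixel_central_moments(pxm)
    ev <- eigen(matrix(c(mom$mu20, mom$mu11, mom$mu11, mom$mu02), 2, 2) /
                  mom$n, symmetric = TRUE, only.values = TRUE)$values
    ax <- 4 * sqrt(pmax(ev, 0)) * mpp
    vrows[[i]] <- data.frame(
      id = i, shape = specs[[i]]$shape, true_class = specs[[i]]$true_class,
      center_x_um = specs[[i]]$center_um[1],
      center_y_um = specs[[i]]$center_um[2],
      caliber_um = specs[[i]]$caliber_um,
      filled_px = nrow(pxm), wall_px = sum(mk$wall),
      area_um2 = nrow(pxm) * mpp^2,
      major_um = ax[1], minor_um = ax[2])
  }
  vessels <- do.call(rbind, vrows)

  # paint: white -> tissue tint -> DAB walls, then noise
  white <- od_to_rgb(c(0, 0, 0))
  tint <- od_to_rgb(tissue_od * stain$hematoxylin_od)
  dabc <- od_to_rgb(vessel_dab_od * stain$dab_od)
  img <- array(0, c(nr, nc, 3))
  for (ch in 1:3) {
    pl <- matrix(white[ch], nr, nc)
    pl[tissue] <- tint[ch]
    pl[wall_all] <- dabc[ch]
    img[, , ch] <- pl
  }
  if (noise_sd > 0) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    img <- img + array(rnorm(length(img), 0, noise_sd * 255), dim(img))
  }
  img <- round(pmin(pmax(img, 0), 255))

  truth <- structure(list(specs = specs,
                          tissue_fraction = mean(tissue),
                          stained_pixel_count = sum(wall_all & tissue),
                          wall_mask = wall_all,
                          filled_labels = filled_labels,
                          vessels = vessels),
                     class = "phantom_truth")
  list(tile = image_tile(img, mpp, sample_id), truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth: %d vessels, tissue fraction %.3f, %d stained px>\n",
              nrow(x$vessels), x$tissue_fraction, x$stained_pixel_count))
  print(table(x$vessels$true_class))
  invisible(x)
}

#' The default 30-vessel phantom layout
#'
#' A fixed layout for a 0.5 x 0.5 mm tile: 10 capillaries (8-12 um), 5
#' post-capillaries & metarterioles (17-18 um), 10 sinusoids (25-45 um) and 5
#' venules & arterioles (62-88 um), mixing closed rings, open rings,
#' elliptical rings, straight tubes, branched (Y) tubes and one star-shaped
#' cistern. Calibers are evenly spaced within each band, at least 2 um from
#' every band edge, and vessels are separated by more than 10 um.
#'
#' @param thresholds [segment_thresholds()] used for the ground-truth classes.
#' @return List of [vessel_spec()] objects.
#' @export
default_phantom_specs <- function(thresholds = segment_thresholds()) {
  sp <- list()
  add <- function(...) sp[[length(sp) + 1]] <<- vessel_spec(
    ..., thresholds = thresholds)
  # capillaries: two rows of 5
  cap <- seq(8, 12, length.out = 10)
  cap_shapes <- c("ring", "ring", "open_ring", "tube", "ring",
                  "ring", "open_ring", "tube", "ring", "ring")
  xs <- c(50, 140, 230, 320, 410)
  for (i in 1:10) {
    y <- if (i <= 5) 40 else 85
    x <- xs[(i - 1) %% 5 + 1]
    if (cap_shapes[i] == "tube")
      add(shape = "tube", center_um = c(x, y), caliber_um = cap[i],
          length_um = 30, rotation = 0.4 * i)
    else if (cap_shapes[i] == "open_ring")
      add(shape = "open_ring", center_um = c(x, y), caliber_um = cap[i],
          gap_fraction = 0.12, rotation = 0.7 * i)
    else
      add(shape = "ring", center_um = c(x, y), caliber_um = cap[i])
  }
  # post-capillaries & metarterioles: one row of 5
  pc <- seq(17, 18, length.out = 5)
  pc_shapes <- c("ring", "ellipse_ring", "ring", "tube", "ring")
  for (i in 1:5) {
    x <- c(60, 160, 260, 360, 445)[i]
    if (pc_shapes[i] == "ellipse_ring")
      add(shape = "ellipse_ring", center_um = c(x, 135), caliber_um = pc[i],
          length_um = 30, rotation = 0.5)
    else if (pc_shapes[i] == "tube")
      add(shape = "tube", center_um = c(x, 135), caliber_um = pc[i],
          length_um = 35, rotation = 1.1)
    else
      add(shape = "ring", center_um = c(x, 135), caliber_um = pc[i])
  }
  # sinusoids: two rows of 5
  si <- seq(25, 45, length.out = 10)
  si_shapes <- c("ellipse_ring", "ring", "branched_tube", "open_ring",
                 "ellipse_ring", "ring", "star_cistern", "ellipse_ring",
                 "ring", "ellipse_ring")
  xs2 <- c(55, 150, 245, 340, 435)
  for (i in 1:10) {
    y <- if (i <= 5) 215 else 305
    x <- xs2[(i - 1) %% 5 + 1]
    s <- si_shapes[i]
    if (s == "ellipse_ring")
      add(shape = "ellipse_ring", center_um = c(x, y), caliber_um = si[i],
          length_um = 1.6 * si[i], wall_thickness_um = 3, rotation = 0.6 * i)
    else if (s == "branched_tube")
      add(shape = "branched_tube", center_um = c(x, y), caliber_um = si[i],
          wall_thickness_um = 3, rotation = 0.3)
    else if (s == "star_cistern")
      add(shape = "star_cistern", center_um = c(x, y), caliber_um = si[i],
          wall_thickness_um = 3, rotation = 0.2)
    else if (s == "open_ring")
      add(shape = "open_ring", center_um = c(x, y), caliber_um = si[i],
          wall_thickness_um = 3, gap_fraction = 0.04, rotation = 2.0)
    else
      add(shape = "ring", center_um = c(x, y), caliber_um = si[i],
          wall_thickness_um = 3)
  }
  # venules & arterioles: one row of 5
  ve <- seq(62, 88, length.out = 5)
  ve_shapes <- c("branched_tube", "ring", "ellipse_ring", "ring", "ring")
  xs3 <- c(52, 148, 242, 343, 448)
  for (i in 1:5) {
    s <- ve_shapes[i]
    if (s == "branched_tube")
      add(shape = "branched_tube", center_um = c(xs3[i], 412),
          caliber_um = ve[i], wall_thickness_um = 4, rotation = 1.2)
    else if (s == "ellipse_ring")
      add(shape = "ellipse_ring", center_um = c(xs3[i], 412),
          caliber_um = ve[i], length_um = 1.3 * ve[i],
          wall_thickness_um = 4, rotation = 0.1)
    else
      add(shape = "ring", center_um = c(xs3[i], 412), caliber_um = ve[i],
          wall_thickness_um = 4)
  }
  sp
}

#' Analytic shape fixtures: exact polygon plus rasterization
#'
#' Returns both the exact generating polygon (for shoelace / arc-length
#' oracles) and its rasterization on an integer pixel grid (for pipeline
#' descriptors).
#'
#' @param kind `"disk"`, `"square"`, `"ellipse"` or `"star"`.
#' @param r disk radius (px).
#' @param side square side (px).
#' @param a,b ellipse semi-axes (px).
#' @param r_outer,r_inner,n_points star radii and point count (px).
#' @param rotation rotation (radians) for ellipse/star.
#' @param n_vertices vertices used to discretize curved outlines.
#' @return List with `polygon` (closed, (row, col) coordinates), `mask`
#'   (logical raster), `center` (row, col).
#' @export
analytic_contour <- function(kind = c("disk", "square", "ellipse", "star"),
                             r = 50, side = 100, a = 40, b = 20,
                             r_outer = 50, r_inner = 20, n_points = 5,
                             rotation = 0, n_vertices = 3600) {
  kind <- match.arg(kind)
  if (kind == "disk") {
    cc <- r + 11
    n <- 2 * cc - 1
    th <- seq(0, 2 * pi, length.out = n_vertices + 1)
    poly <- cbind(cc + r * sin(th), cc + r * cos(th))
    ix <- matrix(rep(seq_len(n), times = n), n, n)
    jx <- matrix(rep(seq_len(n), each = n), n, n)
    mask <- (ix - cc)^2 + (jx - cc)^2 <= r^2
  } else if (kind == "square") {
    o <- 10.5
    poly <- cbind(c(o, o, o + side, o + side, o),
                  c(o, o + side, o + side, o, o))
    n <- side + 21
    ix <- matrix(rep(seq_len(n), times = n), n, n)
    jx <- matrix(rep(seq_len(n), each = n), n, n)
    mask <- ix > o & ix < o + side & jx > o & jx < o + side
    cc <- o + side / 2
  } else if (kind == "ellipse") {
    cc <- ceiling(max(a, b)) + 11
    n <- 2 * cc - 1
    th <- seq(0, 2 * pi, length.out = n_vertices + 1)
    u <- a * cos(th); v <- b * sin(th)
    poly <- cbind(cc + u * sin(rotation) + v * cos(rotation),
                  cc + u * cos(rotation) - v * sin(rotation))
    ix <- matrix(rep(seq_len(n), times = n), n, n)
    jx <- matrix(rep(seq_len(n), each = n), n, n)
    dx <- jx - cc; dy <- ix - cc
    uu <- cos(rotation) * dx + sin(rotation) * dy
    vv <- -sin(rotation) * dx + cos(rotation) * dy
    mask <- (uu / a)^2 + (vv / b)^2 <= 1
  } else {
    cc <- ceiling(r_outer) + 11
    n <- 2 * cc - 1
    sp <- star_polygon(r_outer, r_inner, n_points, rotation)
    poly <- cbind(sp[, 2] + cc, sp[, 1] + cc)   # (row, col) = (y, x)
    mask <- rasterize_polygon(poly, n, n)
  }
  list(polygon = poly, mask = mask, center = c(cc, cc))
}

#' Build a vessel region directly from a binary mask
#'
#' Convenience wrapper around [fill_and_label()] for fixtures and tests:
#' extracts the largest region of `mask` (holes filled by default).
#'
#' @param mask logical matrix.
#' @param microns_per_pixel calibration (um/px).
#' @param include_lumen fill enclosed holes first.
#' @return A `vessel_region`.
#' @export
region_from_mask <- function(mask, microns_per_pixel = 1,
                             include_lumen = TRUE) {
  regs <- fill_and_label(mask != 0, 0, matrix(TRUE, nrow(mask), ncol(mask)),
                         microns_per_pixel, include_lumen)
  if (!length(regs)) stop("empty mask")
  regs[[which.max(vapply(regs, function(r) r$area_px, numeric(1)))]]
}
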