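#' Detect the tissue region of a tile
#'
#' A pixel counts as tissue when it is either visibly coloured (HSV saturation
#' >= `tissue_saturation_min`) or dark (HSV value <= `tissue_value_max`);
#' bright unsaturated pixels are glass/background. Small enclosed holes
#' (< `tissue_max_hole_um2`) are then filled.
#'
#' @param tile an [image_tile()].
#' @param cfg a [stain_config()].
#' @return Logical matrix, `TRUE` on tissue.
#' @export
detect_tissue <- function(tile, cfg) {
  stopifnot(inherits(tile, "image_tile"), inherits(cfg, "stain_config"))
  d <- dim(tile$pixels)
  rgb <- t(matrix(as.numeric(tile$pixels), d[1] * d[2], 3))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  tis <- matrix(hsv[2, ] >= cfg$tissue_saturation_min |
                hsv[3, ] <= cfg$tissue_value_max, d[1], d[2])
  fill_small_holes(tis, cfg$tissue_max_hole_um2 / tile$microns_per_pixel^2)
}

# fill enclosed background holes smaller than max_hole_px pixels
fill_small_holes <- function(mask, max_hole_px) {
  filled <- EBImage::fillHull(mask * 1) > 0
  holes <- filled & !mask
  if (!any(holes)) return(mask)
  lab <- EBImage::bwlabel(holes * 1)
  sizes <- tabulate(lab[lab > 0])
  small <- which(sizes < max_hole_px)
  mask | (matrix(lab %in% small, nrow(mask), ncol(mask)) & holes)
}

#' Threshold the DAB channel into a stained-pixel mask
#'
#' In `"otsu"` mode the cutoff is Otsu's threshold computed on the DAB optical
#' densities of tissue pixels, floored at `cfg$min_dab_od` so a chromogen-free
#' tile yields an empty mask. In `"fixed"` mode `cfg$fixed_dab_threshold` is
#' used directly. Pixels outside the tissue mask are always negative.
#'
#' @param dab_od DAB optical-density matrix from [separate_stains()].
#' @param tissue_mask logical matrix from [detect_tissue()].
#' @param cfg a [stain_config()].
#' @return Logical matrix of CD31-positive pixels (subset of the tissue mask).
#' @export
threshold_dab <- function(dab_od, tissue_mask, cfg) {
  stopifnot(all(dim(dab_od) == dim(tissue_mask)),
            inherits(cfg, "stain_config"))
  if (!any(tissue_mask)) {
    warning("empty tissue mask; returning empty stained mask")
    return(matrix(FALSE, nrow(dab_od), ncol(dab_od)))
  }
  th <- if (cfg$dab_threshold_mode == "fixed") {
    cfg$fixed_dab_threshold
  } else {
    v <- dab_od[tissue_mask]
    hi <- max(v)
    if (hi <= cfg$min_dab_od) {
      Inf                                   # nothing plausibly stained
    } else {
      max(EBImage::otsu(EBImage::Image(matrix(v, nrow = 1)),
                        range = c(0, hi), levels = 256L),
          cfg$min_dab_od)
    }
  }
  dab_od > th & tissue_mask
}

#' Close open endothelial outlines
#'
#' Morphological closing with a disk structuring element of radius
#' `round(closing_radius_um / microns_per_pixel)` px. Gaps in vessel outlines
#' narrower than twice the radius become sealed, so that interrupted
#' endothelial rings can be filled and measured as whole vessels. A radius
#' that maps to 0 px is the identity.
#'
#' @param stained_mask logical matrix of stained pixels.
#' @param closing_radius_um closing radius in um (>= 0).
#' @param microns_per_pixel calibration (um/px).
#' @return Logical matrix; closing is extensive (never removes pixels) and
#'   idempotent.
#' @export
close_open_outlines <- function(stained_mask, closing_radius_um,
                                microns_per_pixel) {
  stopifnot(closing_radius_um >= 0, microns_per_pixel > 0)
  r <- round(closing_radius_um / microns_per_pixel)
  if (r < 1) return(stained_mask != 0)
  brush <- EBImage::makeBrush(2 * r + 1, shape = "disc")
  EBImage::closing(stained_mask * 1, brush) > 0
}

# 8-connected labeling built on EBImage::bwlabel (4-connected) by union-find
# merging of diagonally adjacent labels.
label_regions <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  n <- max(lab)
  if (n <= 1) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]      # NW-SE diagonal pairs
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]     # NE-SW diagonal pairs
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- unique(pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                        pairs[, 1] != pairs[, 2], , drop = FALSE])
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

#' Fill, label and extract vessel regions
#'
#' Enclosed holes (lumina) of each connected component are filled (unless
#' `include_lumen = FALSE`), components are labeled with 8-connectivity,
#' sub-threshold and extra-tissue components are dropped, and each surviving
#' region is returned with its traced outer contour and hole contours.
#'
#' @param closed_mask logical matrix from [close_open_outlines()].
#' @param min_area_um2 minimum filled area (um^2) for a region to be kept.
#' @param tissue_mask logical matrix; regions with less than half their pixels
#'   on tissue are dropped.
#' @param microns_per_pixel calibration (um/px).
#' @param include_lumen fill enclosed holes before measuring (default `TRUE`).
#' @return List of `vessel_region` objects. Each has fields `label`, `pixels`
#'   (n x 2 matrix of (row, col)), `area_px`, `contour` (closed sub-pixel
#'   polygon), `hole_contours`, `touches_border`, and `dim`. The label matrix
#'   of kept regions is attached as attribute `"labels"`.
#' @export
fill_and_label <- function(closed_mask, min_area_um2, tissue_mask,
                           microns_per_pixel, include_lumen = TRUE) {
  stopifnot(all(dim(closed_mask) == dim(tissue_mask)), microns_per_pixel > 0)
  nr <- nrow(closed_mask); nc <- ncol(closed_mask)
  filled <- if (include_lumen) EBImage::fillHull(closed_mask * 1) > 0
            else closed_mask != 0
  lab <- label_regions(filled)
  n <- max(lab)
  if (n == 0) {
    out <- list(); attr(out, "labels") <- lab
    return(out)
  }
  min_px <- min_area_um2 / microns_per_pixel^2
  keep_lab <- matrix(0L, nr, nc)
  regions <- list()
  next_id <- 0L
  for (i in seq_len(n)) {
    sel <- which(lab == i)
    if (length(sel) < max(1, min_px)) next
    rows <- ((sel - 1L) %% nr) + 1L
    cols <- ((sel - 1L) %/% nr) + 1L
    if (mean(tissue_mask[sel]) < 0.5) next
    next_id <- next_id + 1L
    r0 <- min(rows); r1 <- max(rows); c0 <- min(cols); c1 <- max(cols)
    crop <- matrix(FALSE, r1 - r0 + 3, c1 - c0 + 3)
    crop[cbind(rows - r0 + 2L, cols - c0 + 2L)] <- TRUE
    cont <- trace_contours(crop)
    outer <- sweep(cont[[1]], 2, c(r0 - 2L, c0 - 2L), "+")
    holes <- list()
    if (include_lumen) {
      lum <- crop & !{
        cm <- matrix(FALSE, r1 - r0 + 3, c1 - c0 + 3)
        cs <- which(closed_mask[r0:r1, c0:c1], arr.ind = TRUE)
        if (nrow(cs)) cm[cbind(cs[, 1] + 1L, cs[, 2] + 1L)] <- TRUE
        cm
      }
      if (any(lum))
        holes <- lapply(trace_contours(lum),
                        function(p) sweep(p, 2, c(r0 - 2L, c0 - 2L), "+"))
    }
    keep_lab[sel] <- next_id
    regions[[next_id]] <- structure(
      list(label = next_id,
           pixels = cbind(row = rows, col = cols),
           area_px = length(sel),
           contour = outer,
           hole_contours = holes,
           touches_border = any(rows == 1L | rows == nr |
                                cols == 1L | cols == nc),
           dim = c(nr, nc)),
      class = "vessel_region")
  }
  attr(regions, "labels") <- keep_lab
  regions
}

#' @export
print.vessel_region <- function(x, ...) {
  cat(sprintf("<vessel_region #%d: %d px%s>\n", x$label, x$area_px,
              if (x$touches_border) ", touches border" else ""))
  invisible(x)
}

#' Segment vessels in a calibrated tile
#'
#' Runs stain separation, tissue detection, DAB thresholding, outline closing
#' and region extraction in sequence.
#'
#' @param tile an [image_tile()].
#' @param cfg a [run_config()].
#' @return List with `masks` (class `mask_set`: logical `tissue`, `stained`,
#'   `vessel` matrices plus the integer `labels` matrix) and `regions` (list
#'   of `vessel_region`).
#' @export
segment_vessels <- function(tile, cfg = run_config()) {
  stopifnot(inherits(tile, "image_tile"), inherits(cfg, "run_config"))
  dab <- separate_stains(tile, cfg$stain)
  tissue <- detect_tissue(tile, cfg$stain)
  stained <- threshold_dab(dab, tissue, cfg$stain)
  vessel <- close_open_outlines(stained, cfg$closing_radius_um,
                                tile$microns_per_pixel)
  regions <- fill_and_label(vessel, cfg$min_area_um2, tissue,
                            tile$microns_per_pixel, cfg$include_lumen)
  masks <- structure(list(tissue = tissue, stained = stained, vessel = vessel,
                          labels = attr(regions, "labels")),
                     class = "mask_set")
  list(masks = masks, regions = regions)
}
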