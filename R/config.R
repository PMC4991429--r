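#' Stain separation and masking configuration
#'
#' Bundles the optical-density (OD) stain vectors and the thresholds used to
#' build the tissue and stained-pixel masks. Defaults are the standard
#' Ruifrok-Johnston H-DAB basis; both vectors are renormalised to unit
#' Euclidean length on construction.
#'
#' @param hematoxylin_od numeric(3), OD direction of the hematoxylin
#'   counterstain.
#' @param dab_od numeric(3), OD direction of the DAB chromogen.
#' @param dab_threshold_mode `"otsu"` (threshold chosen by Otsu's method on
#'   within-tissue DAB OD) or `"fixed"`.
#' @param fixed_dab_threshold OD cutoff used when `dab_threshold_mode` is
#'   `"fixed"`.
#' @param min_dab_od floor applied to the Otsu threshold, so a chromogen-free
#'   tile yields an empty stained mask rather than a split of background noise.
#' @param tissue_saturation_min minimum HSV saturation for a pixel to count as
#'   tissue.
#' @param tissue_value_max maximum HSV value (brightness) below which a pixel
#'   counts as tissue regardless of saturation.
#' @param tissue_max_hole_um2 holes in the tissue mask smaller than this area
#'   (um^2) are filled.
#'
#' @return An object of class `stain_config`.
#' @export
#' @examples
#' cfg <- stain_config()
#' cfg$dab_od
stain_config <- function(hematoxylin_od = c(0.650, 0.704, 0.286),
                         dab_od = c(0.269, 0.568, 0.872),
                         dab_threshold_mode = c("otsu", "fixed"),
                         fixed_dab_threshold = 0.3,
                         min_dab_od = 0.1,
                         tissue_saturation_min = 0.08,
                         tissue_value_max = 0.85,
                         tissue_max_hole_um2 = 1000) {
  dab_threshold_mode <- match.arg(dab_threshold_mode)
  stopifnot(length(hematoxylin_od) == 3, length(dab_od) == 3,
            all(is.finite(hematoxylin_od)), all(is.finite(dab_od)),
            fixed_dab_threshold >= 0, min_dab_od >= 0,
            tissue_saturation_min >= 0, tissue_saturation_min <= 1,
            tissue_value_max >= 0, tissue_value_max <= 1)
  h <- hematoxylin_od / sqrt(sum(hematoxylin_od^2))
  d <- dab_od / sqrt(sum(dab_od^2))
  if (sqrt(sum(vm_cross(h, d)^2)) < 1e-6)
    stop("stain vectors are collinear; cannot deconvolve")
  structure(list(hematoxylin_od = h, dab_od = d,
                 dab_threshold_mode = dab_threshold_mode,
                 fixed_dab_threshold = fixed_dab_threshold,
                 min_dab_od = min_dab_od,
                 tissue_saturation_min = tissue_saturation_min,
                 tissue_value_max = tissue_value_max,
                 tissue_max_hole_um2 = tissue_max_hole_um2),
            class = "stain_config")
}

vm_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Caliber thresholds for microvascular segment classification
#'
#' Width bands (equivalent-ellipse minor axis, um) separating the five
#' microvascular segments. The capillary (5-15 um) and sinusoid (20-50 um)
#' calibers follow the morphology of CD31-stained neuroblastic tumours; the
#' remaining bands interpolate/extrapolate consistently with vascular
#' physiology and are fully configurable. Intervals are half-open: a width
#' exactly on a boundary belongs to the upper class.
#'
#' @param min_width vessels narrower than this (um) are excluded from
#'   classification (recorded with an `NA` class).
#' @param capillary_max,postcap_max,sinusoid_max,venule_max upper band edges
#'   (um) for capillaries, post-capillaries & metarterioles, sinusoids, and
#'   venules & arterioles; wider vessels are veins & arteries.
#' @return An object of class `segment_thresholds`.
#' @export
segment_thresholds <- function(min_width = 3, capillary_max = 15,
                               postcap_max = 20, sinusoid_max = 50,
                               venule_max = 100) {
  edges <- c(min_width, capillary_max, postcap_max, sinusoid_max, venule_max)
  if (any(diff(edges) <= 0))
    stop("thresholds must satisfy min_width < capillary_max < postcap_max ",
         "< sinusoid_max < venule_max")
  structure(list(min_width = min_width, capillary_max = capillary_max,
                 postcap_max = postcap_max, sinusoid_max = sinusoid_max,
                 venule_max = venule_max),
            class = "segment_thresholds")
}

#' Pipeline run configuration
#'
#' @param inputs character vector of image paths, or a single glob pattern
#'   (expanded with [Sys.glob()]).
#' @param microns_per_pixel image calibration (um/px, > 0).
#' @param stain a [stain_config()].
#' @param thresholds a [segment_thresholds()].
#' @param closing_radius_um radius (um) of the disk structuring element used
#'   to seal open endothelial outlines.
#' @param min_area_um2 filled regions smaller than this (um^2) are discarded.
#' @param exclude_border_from_shape if `TRUE` (default) border-touching
#'   vessels count toward density and stained area but are excluded from
#'   size/shape means (their geometry is truncated by the tile edge).
#' @param include_lumen if `TRUE` (default) enclosed lumina are filled so
#'   size descriptors reflect the full caliber (wall + lumen).
#' @param hu_index_set Hu-moment indices used by the shape factor.
#' @param axis_mode `"ellipse"` (equivalent-ellipse axes; default) or
#'   `"feret"` (maximal/minimal Feret diameters) for length/width.
#' @param out_dir output directory for [run_batch()].
#' @param write_masks write mask/label/overlay images in [run_batch()].
#' @param seed integer seed for any stochastic utilities.
#' @return An object of class `run_config`.
#' @export
run_config <- function(inputs = character(), microns_per_pixel = 0.25,
                       stain = stain_config(),
                       thresholds = segment_thresholds(),
                       closing_radius_um = 2.5, min_area_um2 = 12,
                       exclude_border_from_shape = TRUE,
                       include_lumen = TRUE,
                       hu_index_set = 1:7,
                       axis_mode = c("ellipse", "feret"),
                       out_dir = "vesselmorph_out", write_masks = TRUE,
                       seed = 1L) {
  axis_mode <- match.arg(axis_mode)
  stopifnot(is.numeric(microns_per_pixel), microns_per_pixel > 0,
            is.finite(microns_per_pixel),
            inherits(stain, "stain_config"),
            inherits(thresholds, "segment_thresholds"),
            closing_radius_um >= 0, min_area_um2 >= 0,
            all(hu_index_set %in% 1:7))
  structure(list(inputs = inputs, microns_per_pixel = microns_per_pixel,
                 stain = stain, thresholds = thresholds,
                 closing_radius_um = closing_radius_um,
                 min_area_um2 = min_area_um2,
                 exclude_border_from_shape = exclude_border_from_shape,
                 include_lumen = include_lumen,
                 hu_index_set = as.integer(hu_index_set),
                 axis_mode = axis_mode,
                 out_dir = out_dir, write_masks = write_masks,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognised top-level keys mirror the arguments of [run_config()]; `stain`
#' and `thresholds` are nested maps passed to [stain_config()] and
#' [segment_thresholds()]. Unknown keys are an error.
#'
#' @param path YAML file.
#' @param ... overrides applied after the file is read (e.g.
#'   `microns_per_pixel = 0.5`).
#' @return A `run_config` object.
#' @export
read_run_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  over <- list(...)
  raw[names(over)] <- over
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(raw$stain) && !inherits(raw$stain, "stain_config"))
    raw$stain <- do.call(stain_config, raw$stain)
  if (!is.null(raw$thresholds) && !inherits(raw$thresholds, "segment_thresholds"))
    raw$thresholds <- do.call(segment_thresholds, raw$thresholds)
  do.call(run_config, raw)
}
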