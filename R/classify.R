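#' Microvascular segment classes
#'
#' Factor levels used throughout: capillary, post-capillary & metarteriole,
#' sinusoid, venule & arteriole, vein & artery.
#'
#' @return Character vector of the five segment class names, in caliber order.
#' @export
segment_classes <- function() .vm_segment_levels

#' Classify a vessel into a microvascular segment by caliber
#'
#' The classifying caliber is the vessel width (equivalent-ellipse minor
#' axis), robust to elongation. Bands are half-open, the boundary belonging
#' to the upper class: `[min_width, capillary_max)` capillary,
#' `[capillary_max, postcap_max)` post-capillary & metarteriole,
#' `[postcap_max, sinusoid_max)` sinusoid, `[sinusoid_max, venule_max)`
#' venule & arteriole, `>= venule_max` vein & artery.
#'
#' @param width_um vessel width(s) in um (vectorized).
#' @param thresholds a [segment_thresholds()].
#' @return Factor with levels [segment_classes()]; widths below `min_width`
#'   give `NA` with a warning (the vessel is excluded from classification).
#' @export
#' @examples
#' classify_vessel(c(10, 30, 15), segment_thresholds())
classify_vessel <- function(width_um, thresholds = segment_thresholds()) {
  stopifnot(inherits(thresholds, "segment_thresholds"), all(width_um > 0))
  br <- c(thresholds$min_width, thresholds$capillary_max,
          thresholds$postcap_max, thresholds$sinusoid_max,
          thresholds$venule_max, Inf)
  cls <- cut(width_um, breaks = br, labels = .vm_segment_levels,
             right = FALSE)
  if (anyNA(cls))
    warning(sum(is.na(cls)), " vessel(s) below min_width (",
            thresholds$min_width, " um) excluded from classification")
  factor(cls, levels = .vm_segment_levels)
}

#' Summarise the vessels of one sample
#'
#' Computes the per-sample quantity statistics: tissue area, total vessel
#' density (vessels/mm^2), total stained-area percentage, and per-segment
#' count, density, SA%, relative density and relative SA, plus descriptor
#' means. SA is measured on the raw stained mask (endothelial staining)
#' restricted to vessel regions; densities count every classified vessel
#' (border-touching included); descriptor means are taken over non-border
#' vessels when `exclude_border_from_shape` is `TRUE`.
#'
#' @param vessels `data.frame` from [measure_regions()] with added columns
#'   `segment_class` (factor) and `stained_px` (stained pixels inside each
#'   region; optional, defaults to 0).
#' @param masks a `mask_set` from [segment_vessels()].
#' @param microns_per_pixel calibration (um/px).
#' @param sample_id sample label.
#' @param exclude_border_from_shape drop border-touching vessels from
#'   descriptor means.
#' @return List of class `sample_summary`: `sample` (one-row wide
#'   `data.frame`) and `segments` (long `data.frame`, one row per segment
#'   with quantity statistics and descriptor means).
#' @export
summarize_sample <- function(vessels, masks, microns_per_pixel,
                             sample_id = "sample",
                             exclude_border_from_shape = TRUE) {
  tissue_px <- sum(masks$tissue)
  if (tissue_px == 0) stop("zero tissue area")
  tissue_mm2 <- tissue_px * microns_per_pixel^2 / 1e6
  if (is.null(vessels$stained_px)) vessels$stained_px <- 0
  cls <- vessels$segment_class
  keep <- !is.na(cls)
  v <- vessels[keep, , drop = FALSE]
  n_tot <- nrow(v)

  desc_cols <- c("area_um2", "length_um", "width_um", "perimeter_um",
                 "aspect", "roundness", "perimeter_ratio", "deformity_um2",
                 "shape_factor", "branch_count")
  shape_v <- if (exclude_border_from_shape)
    v[!v$touches_border, , drop = FALSE] else v

  seg_stats <- lapply(.vm_segment_levels, function(s) {
    vs <- v[v$segment_class == s, , drop = FALSE]
    ss <- shape_v[shape_v$segment_class == s, , drop = FALSE]
    means <- if (nrow(ss)) colMeans(ss[desc_cols]) else
      stats::setNames(rep(NA_real_, length(desc_cols)), desc_cols)
    data.frame(sample_id = sample_id, segment_class = s,
               count = nrow(vs),
               density = nrow(vs) / tissue_mm2,
               sa_percent = 100 * sum(vs$stained_px) / tissue_px,
               relative_density = if (n_tot) 100 * nrow(vs) / n_tot
                                  else NA_real_,
               relative_sa = if (sum(v$stained_px) > 0)
                 100 * sum(vs$stained_px) / sum(v$stained_px) else NA_real_,
               t(means))
  })
  segments <- do.call(rbind, seg_stats)
  rownames(segments) <- NULL

  tot_means <- if (nrow(shape_v)) colMeans(shape_v[desc_cols]) else
    stats::setNames(rep(NA_real_, length(desc_cols)), desc_cols)
  wide <- data.frame(sample_id = sample_id,
                     tissue_area_mm2 = tissue_mm2,
                     n_vessels = n_tot,
                     total_density = n_tot / tissue_mm2,
                     total_sa_percent = 100 * sum(v$stained_px) / tissue_px,
                     t(stats::setNames(tot_means, paste0("mean_", desc_cols))))
  for (s in .vm_segment_levels) {
    row <- segments[segments$segment_class == s, ]
    for (f in c("count", "density", "sa_percent", "relative_density",
                "relative_sa"))
      wide[[paste(s, f, sep = "_")]] <- row[[f]]
  }
  structure(list(sample = wide, segments = segments),
            class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  s <- x$sample
  cat(sprintf("<sample_summary '%s': %.3g mm^2 tissue, %d vessels, %.3g/mm^2, SA %.3g%%>\n",
              s$sample_id, s$tissue_area_mm2, s$n_vessels, s$total_density,
              s$total_sa_percent))
  print(x$segments[c("segment_class", "count", "density", "sa_percent",
                     "relative_density", "relative_sa")])
  invisible(x)
}
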