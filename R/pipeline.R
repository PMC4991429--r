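#' Analyse one calibrated tile
#'
#' Full pipeline for a single tile: segmentation, per-vessel morphometry,
#' caliber classification and the per-sample summary.
#'
#' @param tile an [image_tile()].
#' @param cfg a [run_config()].
#' @return List with `masks` (`mask_set`), `regions`, `vessels` (per-vessel
#'   `data.frame` incl. `segment_class` and `stained_px`) and `summary`
#'   (`sample_summary`).
#' @export
analyze_tile <- function(tile, cfg = run_config()) {
  seg <- suppressWarnings(segment_vessels(tile, cfg))
  if (!any(seg$masks$tissue)) {
    warning(sprintf("[%s] no tissue detected; emitting a zero-area summary",
                    tile$sample_id))
    return(list(masks = seg$masks, regions = seg$regions,
                vessels = empty_vessel_table(),
                summary = empty_sample_summary(tile$sample_id)))
  }
  vessels <- measure_regions(seg$regions, tile$microns_per_pixel,
                             cfg$hu_index_set, cfg$axis_mode)
  if (nrow(vessels)) {
    vessels$segment_class <- suppressWarnings(
      classify_vessel(vessels$width_um, cfg$thresholds))
    n_ex <- sum(is.na(vessels$segment_class))
    if (n_ex > 0)
      message(sprintf("[%s] %d vessel(s) below min_width excluded",
                      tile$sample_id, n_ex))
    lab <- seg$masks$labels
    stained_lab <- lab[seg$masks$stained & lab > 0]
    cnt <- tabulate(stained_lab, nbins = max(vessels$label))
    vessels$stained_px <- cnt[vessels$label]
    vessels <- cbind(sample_id = tile$sample_id, vessels)
  } else {
    vessels <- cbind(sample_id = character(0), vessels,
                     segment_class = factor(character(0),
                                            levels = segment_classes()),
                     stained_px = integer(0))
  }
  summary <- summarize_sample(vessels, seg$masks, tile$microns_per_pixel,
                              tile$sample_id, cfg$exclude_border_from_shape)
  list(masks = seg$masks, regions = seg$regions, vessels = vessels,
       summary = summary)
}

#' Render the binarized vessel view
#'
#' Detected (filled) vessels in white on a black background.
#'
#' @param regions list of `vessel_region`.
#' @param dims integer(2) raster dimensions; defaults to the regions' tile
#'   dimensions.
#' @return Logical matrix; all-`FALSE` (pure black) for an empty region list.
#' @export
render_binarized <- function(regions, dims = NULL) {
  if (is.null(dims)) {
    if (!length(regions)) stop("dims required for an empty region list")
    dims <- regions[[1]]$dim
  }
  out <- matrix(FALSE, dims[1], dims[2])
  for (rg in regions) out[rg$pixels] <- TRUE
  out
}

#' Render a class-coloured overlay of detected vessels
#'
#' @param tile an [image_tile()].
#' @param regions list of `vessel_region`.
#' @param classes factor of segment classes, parallel to `regions`.
#' @return `h x w x 3` array (0-255): detected vessel pixels coloured by
#'   segment class on the (dimmed) original image; an empty region list gives
#'   the dimmed image unchanged.
#' @export
render_overlay <- function(tile, regions, classes) {
  pal <- c(capillary = c(230, 60, 60), postcapillary_metarteriole =
             c(240, 160, 40), sinusoid = c(60, 170, 60),
           venule_arteriole = c(70, 110, 230), vein_artery = c(170, 70, 200))
  pal <- matrix(unlist(pal), nrow = 3)
  colnames(pal) <- segment_classes()
  img <- array(as.numeric(tile$pixels) * 0.5, dim(tile$pixels))
  for (i in seq_along(regions)) {
    cl <- as.character(classes[i])
    col <- if (!is.na(cl) && cl %in% colnames(pal)) pal[, cl] else c(120, 120, 120)
    idx <- (regions[[i]]$pixels[, 2] - 1L) * dim(img)[1] + regions[[i]]$pixels[, 1]
    npx <- dim(img)[1] * dim(img)[2]
    for (ch in 1:3) img[idx + (ch - 1L) * npx] <- col[ch]
  }
  img
}

#' Run the batch pipeline over a set of tiles
#'
#' Processes every input tile independently and deterministically, writes the
#' per-vessel and per-sample CSV tables (comma-separated, UTF-8, `.` decimal,
#' fixed column order), optional mask/label/overlay images, and a JSON run
#' manifest with config echo and per-file MD5 checksums. A tile that fails to
#' load is logged and skipped.
#'
#' @param cfg a [run_config()] whose `inputs` name at least one readable
#'   image (paths or a glob pattern).
#' @return Invisibly, a list with `vessels`, `samples`, `segments`
#'   (`data.frame`s) and `manifest` (list); all files are written under
#'   `cfg$out_dir`.
#' @export
run_batch <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  paths <- cfg$inputs
  if (length(paths) == 1 && !file.exists(paths)) paths <- Sys.glob(paths)
  paths <- sort(unique(paths))
  if (!length(paths)) stop("no readable inputs")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  vessel_rows <- list(); sample_rows <- list(); segment_rows <- list()
  counts <- list()
  for (p in paths) {
    tile <- tryCatch(read_tile(p, cfg$microns_per_pixel),
                     error = function(e) {
                       warning("skipping unreadable tile ", p, ": ",
                               conditionMessage(e))
                       NULL
                     })
    if (is.null(tile)) next
    res <- analyze_tile(tile, cfg)
    vessel_rows[[tile$sample_id]] <- res$vessels
    sample_rows[[tile$sample_id]] <- res$summary$sample
    segment_rows[[tile$sample_id]] <- res$summary$segments
    counts[[tile$sample_id]] <- nrow(res$vessels)
    if (cfg$write_masks) {
      base <- file.path(cfg$out_dir, tile$sample_id)
      write_mask_png(res$masks$stained, paste0(base, "_stained.png"))
      write_mask_png(render_binarized(res$regions, dim(res$masks$tissue)),
                     paste0(base, "_vessels.png"))
      write_labels_tiff(res$masks$labels, paste0(base, "_labels.tiff"))
      ov <- render_overlay(tile, res$regions, res$vessels$segment_class)
      write_mask_png(ov, paste0(base, "_overlay.png"))
    }
  }
  if (!length(sample_rows)) stop("no readable inputs")

  vessels <- do.call(rbind, c(vessel_rows, list(make.row.names = FALSE)))
  samples <- do.call(rbind, c(sample_rows, list(make.row.names = FALSE)))
  segments <- do.call(rbind, c(segment_rows, list(make.row.names = FALSE)))
  vf <- file.path(cfg$out_dir, "vessels.csv")
  sf <- file.path(cfg$out_dir, "samples.csv")
  gf <- file.path(cfg$out_dir, "segments.csv")
  write.csv(vessels, vf, row.names = FALSE, fileEncoding = "UTF-8")
  write.csv(samples, sf, row.names = FALSE, fileEncoding = "UTF-8")
  write.csv(segments, gf, row.names = FALSE, fileEncoding = "UTF-8")

  cfg_txt <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config_as_list(cfg), cfg_txt)
  outputs <- setdiff(list.files(cfg$out_dir, full.names = TRUE),
                     file.path(cfg$out_dir, "manifest.json"))
  manifest <- list(
    tool = "vesselmorph",
    version = as.character(utils::packageVersion("vesselmorph")),
    config = config_as_list(cfg),
    config_md5 = unname(tools::md5sum(cfg_txt)),
    inputs = paths,
    vessel_counts = counts,
    outputs = lapply(sort(outputs), function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  unlink(cfg_txt)
  invisible(list(vessels = vessels, samples = samples, segments = segments,
                 manifest = manifest))
}

empty_vessel_table <- function() {
  cbind(sample_id = character(0),
        measure_regions(list(), 1),
        segment_class = factor(character(0), levels = segment_classes()),
        stained_px = integer(0))
}

# degenerate per-sample summary for a tile with no detectable tissue:
# tissue_area_mm2 = 0 flags the row; densities/SA are undefined
empty_sample_summary <- function(sample_id) {
  masks <- structure(list(tissue = matrix(TRUE, 1, 1)), class = "mask_set")
  s <- suppressWarnings(summarize_sample(empty_vessel_table(), masks, 1,
                                         sample_id))
  s$sample$tissue_area_mm2 <- 0
  for (f in grep("density|sa_percent|relative", names(s$sample), value = TRUE))
    s$sample[[f]] <- NA_real_
  for (f in c("density", "sa_percent", "relative_density", "relative_sa"))
    s$segments[[f]] <- NA_real_
  s
}

# plain-list view of a run_config for YAML/JSON serialisation
config_as_list <- function(cfg) {
  x <- unclass(cfg)
  x$stain <- unclass(x$stain)
  x$thresholds <- unclass(x$thresholds)
  x
}

#' Write a phantom tile, its ground truth and its spec file
#'
#' Companion to [render_phantom_tile()] for shell use: writes the rendered
#' tile (PNG), a ground-truth CSV and a YAML file of the generating specs.
#'
#' @param phantom result of [render_phantom_tile()].
#' @param out_dir output directory.
#' @param name base file name.
#' @return Invisibly, the written paths.
#' @export
write_phantom <- function(phantom, out_dir, name = "phantom") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  img <- file.path(out_dir, paste0(name, ".png"))
  png::writePNG(phantom$tile$pixels / 255, img)
  gt <- file.path(out_dir, paste0(name, "_truth.csv"))
  write.csv(phantom$truth$vessels, gt, row.names = FALSE,
            fileEncoding = "UTF-8")
  sp <- file.path(out_dir, paste0(name, "_specs.yaml"))
  yaml::write_yaml(lapply(phantom$truth$specs, unclass), sp)
  invisible(c(image = img, truth = gt, specs = sp))
}
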