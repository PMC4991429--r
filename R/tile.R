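#' Construct a calibrated RGB image tile
#'
#' The unit of processing: an 8-bit RGB raster with a physical length scale.
#'
#' @param pixels numeric or integer array `height x width x 3` with values in
#'   `[0, 255]`.
#' @param microns_per_pixel physical calibration (um/px, finite and > 0).
#' @param sample_id text label used in all output tables.
#' @return An object of class `image_tile`.
#' @export
image_tile <- function(pixels, microns_per_pixel, sample_id = "sample") {
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    stop("pixels must be a height x width x 3 array")
  if (any(dim(pixels)[1:2] < 1)) stop("pixels must be non-empty")
  if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1 ||
      !is.finite(microns_per_pixel) || microns_per_pixel <= 0)
    stop("microns_per_pixel must be a single finite value > 0")
  storage.mode(pixels) <- "integer"
  if (min(pixels) < 0L || max(pixels) > 255L)
    stop("pixel values must lie in [0, 255]")
  structure(list(pixels = pixels,
                 microns_per_pixel = as.numeric(microns_per_pixel),
                 sample_id = as.character(sample_id)),
            class = "image_tile")
}

#' @export
print.image_tile <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_tile '%s': %d x %d px at %.4g um/px (%.3g x %.3g um)>\n",
              x$sample_id, d[1], d[2], x$microns_per_pixel,
              d[1] * x$microns_per_pixel, d[2] * x$microns_per_pixel))
  invisible(x)
}

#' Read an RGB tile from a PNG or TIFF file
#'
#' @param path image file (`.png`, `.tif`, `.tiff`).
#' @param microns_per_pixel calibration to attach (um/px).
#' @param sample_id label; defaults to the file name without extension.
#' @return An `image_tile`.
#' @export
read_tile <- function(path, microns_per_pixel,
                      sample_id = tools::file_path_sans_ext(basename(path))) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext))
  if (length(dim(img)) == 2) img <- array(img, c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  image_tile(round(img * 255), microns_per_pixel, sample_id)
}

#' Write an RGB array or binary mask as PNG
#'
#' Masks are written as single-channel 0/255 images; RGB arrays (values in
#' `[0, 255]`) as colour PNG.
#'
#' @param x logical matrix (mask) or `h x w x 3` array.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(x, path) {
  if (is.matrix(x)) {
    png::writePNG(matrix(as.numeric(x != 0), nrow(x), ncol(x)), path)
  } else {
    png::writePNG(x / 255, path)
  }
  invisible(path)
}

#' Write a label matrix as 16-bit TIFF
#'
#' @param labels integer matrix of region labels (0 = background).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_labels_tiff <- function(labels, path) {
  if (max(labels) > 65535) stop("more than 65535 labels")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}
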