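#' Colour deconvolution: extract the DAB optical-density channel
#'
#' Converts the RGB tile to optical density, `OD = -log10((I + 1) / 256)`
#' per channel, and unmixes it against the two-stain basis (hematoxylin, DAB,
#' plus the normalised cross-product of the two as residual axis). Negative
#' projections are clamped to zero.
#'
#' @param tile an [image_tile()].
#' @param cfg a [stain_config()].
#' @return Numeric matrix (`height x width`) of per-pixel DAB optical density,
#'   >= 0.
#' @export
#' @examples
#' px <- array(255L, c(4, 4, 3))   # pure white: zero optical density
#' separate_stains(image_tile(px, 0.25), stain_config())
separate_stains <- function(tile, cfg) {
  stopifnot(inherits(tile, "image_tile"), inherits(cfg, "stain_config"))
  M <- stain_basis(cfg)
  d <- dim(tile$pixels)
  od <- -log10((matrix(as.numeric(tile$pixels), d[1] * d[2], 3) + 1) / 256)
  conc <- od %*% t(solve(M))
  dab <- pmax(conc[, 2], 0)
  matrix(dab, d[1], d[2])
}

# 3x3 basis with stain vectors as columns: [hematoxylin, DAB, residual]
stain_basis <- function(cfg) {
  r <- vm_cross(cfg$hematoxylin_od, cfg$dab_od)
  nr <- sqrt(sum(r^2))
  if (nr < 1e-6) stop("stain vectors are collinear; cannot deconvolve")
  cbind(cfg$hematoxylin_od, cfg$dab_od, r / nr)
}

# inverse of the OD transform: intensity (0..255) for a given OD 3-vector
od_to_rgb <- function(od) {
  pmin(pmax(round(256 * 10^(-od) - 1), 0), 255)
}
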