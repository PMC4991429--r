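# Independent oracles for the descriptor tests. These deliberately avoid the
# package's vectorized moment/geometry code paths: polygon quantities are
# accumulated edge by edge, and raster moments pixel by pixel with explicit
# loops, so agreement is a genuine cross-check.

# shoelace area of a closed polygon, edge-by-edge accumulation
oracle_polygon_area <- function(poly) {
  s <- 0
  for (i in seq_len(nrow(poly) - 1)) {
    s <- s + poly[i, 1] * poly[i + 1, 2] - poly[i + 1, 1] * poly[i, 2]
  }
  abs(s) / 2
}

# arc length of a closed polygon, edge-by-edge accumulation
oracle_polygon_perimeter <- function(poly) {
  s <- 0
  for (i in seq_len(nrow(poly) - 1)) {
    s <- s + sqrt(sum((poly[i + 1, ] - poly[i, ])^2))
  }
  s
}

# brute-force raw-moment double sum over a raster mask, then Hu invariants.
oracle_hu <- function(mask) {
  m00 <- m10 <- m01 <- m20 <- m02 <- m11 <- 0
  m30 <- m03 <- m21 <- m12 <- 0
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (mask[i, j]) {
        m00 <- m00 + 1
        m10 <- m10 + i;       m01 <- m01 + j
        m20 <- m20 + i^2;     m02 <- m02 + j^2;     m11 <- m11 + i * j
        m30 <- m30 + i^3;     m03 <- m03 + j^3
        m21 <- m21 + i^2 * j; m12 <- m12 + i * j^2
      }
    }
  }
  xb <- m10 / m00; yb <- m01 / m00
  mu <- c(p20 = m20 - m00 * xb^2,
          p02 = m02 - m00 * yb^2,
          p11 = m11 - m00 * xb * yb,
          p30 = m30 - 3 * xb * m20 + 2 * m00 * xb^3,
          p03 = m03 - 3 * yb * m02 + 2 * m00 * yb^3,
          p21 = m21 - 2 * xb * m11 - yb * m20 + 2 * m00 * xb^2 * yb,
          p12 = m12 - 2 * yb * m11 - xb * m02 + 2 * m00 * xb * yb^2)
  e <- c(mu["p20"], mu["p02"], mu["p11"]) / m00^2
  f <- c(mu["p30"], mu["p03"], mu["p21"], mu["p12"]) / m00^2.5
  n20 <- e[[1]]; n02 <- e[[2]]; n11 <- e[[3]]
  n30 <- f[[1]]; n03 <- f[[2]]; n21 <- f[[3]]; n12 <- f[[4]]
  c((n20 + n02),
    (n20 - n02)^2 + 4 * n11^2,
    (n30 - 3 * n12)^2 + (3 * n21 - n03)^2,
    (n30 + n12)^2 + (n21 + n03)^2,
    (n30 - 3 * n12) * (n30 + n12) * ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
      (3 * n21 - n03) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2),
    (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
      4 * n11 * (n30 + n12) * (n21 + n03),
    (3 * n21 - n03) * (n30 + n12) * ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
      (n30 - 3 * n12) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2))
}

# random smooth radial polygon (closed, (row, col)), for moment cross-checks
random_radial_polygon <- function(center = c(31, 31), base_r = 22,
                                  n_vert = 72) {
  k <- 1:3
  a <- runif(3, -0.2, 0.2); b <- runif(3, -0.2, 0.2)
  th <- seq(0, 2 * pi, length.out = n_vert + 1)[-(n_vert + 1)]
  r <- base_r * (1 + sapply(th, function(t)
    sum(a * cos(k * t) + b * sin(k * t))))
  r <- pmax(r, 3)
  v <- cbind(center[1] + r * sin(th), center[2] + r * cos(th))
  rbind(v, v[1, ])
}

# small phantom used by pipeline tests: 6 vessels on a 200 x 200 um tile
small_phantom_specs <- function() {
  list(
    vessel_spec("ring", c(40, 40), 10),
    vessel_spec("open_ring", c(110, 40), 11, gap_fraction = 0.12,
                rotation = 0.8),
    vessel_spec("tube", c(165, 45), 9, length_um = 28, rotation = 0.5),
    vessel_spec("ring", c(50, 115), 17.5),
    vessel_spec("ellipse_ring", c(145, 115), 30, length_um = 48,
                wall_thickness_um = 3, rotation = 0.3),
    vessel_spec("ring", c(95, 168), 35, wall_thickness_um = 3))
}

render_small_phantom <- function(seed = 11) {
  render_phantom_tile(small_phantom_specs(), tile_size_um = c(200, 200),
                      microns_per_pixel = 0.5, seed = seed,
                      sample_id = paste0("phantom_s", seed))
}
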