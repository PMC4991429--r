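cfg <- stain_config()

test_that("tissue detection separates tint from glass", {
  tint <- c(203L, 200L, 231L)    # hematoxylin tint, OD ~0.15
  white_tile <- image_tile(array(255L, c(40, 40, 3)), 1)
  expect_equal(sum(detect_tissue(white_tile, cfg)), 0)

  px <- array(rep(tint, each = 1600), c(40, 40, 3))
  expect_equal(mean(detect_tissue(image_tile(px, 1), cfg)), 1)

  # half white, half tinted: tissue fraction 0.5 by pixel count
  half <- array(255L, c(40, 40, 3))
  for (ch in 1:3) half[, 1:20, ch] <- tint[ch]
  frac <- mean(detect_tissue(image_tile(half, 1), cfg))
  expect_equal(frac, 0.5, tolerance = 0.01)
})

test_that("small tissue holes are filled, large ones kept", {
  tint <- c(203L, 200L, 231L)
  px <- array(rep(tint, each = 10000), c(100, 100, 3))
  px[48:52, 48:52, ] <- 255L       # 25 um^2 hole at 1 um/px -> filled
  px[10:40, 60:95, ] <- 255L       # 1116 um^2 hole -> kept
  tis <- detect_tissue(image_tile(px, 1), cfg)
  expect_true(all(tis[48:52, 48:52]))
  expect_true(!any(tis[11:39, 61:94]))
})

test_that("DAB thresholding respects mode, tissue mask and degenerate input", {
  tis <- matrix(TRUE, 50, 50)
  # all-zero OD: empty mask (Otsu floor)
  expect_equal(sum(threshold_dab(matrix(0, 50, 50), tis, cfg)), 0)
  # bimodal: background 0.05, rings 0.9 -> exactly the ring pixels
  od <- matrix(0.05, 50, 50)
  ring <- (row(od) - 25)^2 + (col(od) - 25)^2 <= 15^2 &
          (row(od) - 25)^2 + (col(od) - 25)^2 >= 12^2
  od[ring] <- 0.9
  expect_identical(unname(threshold_dab(od, tis, cfg)), ring)
  # fixed threshold
  fcfg <- stain_config(dab_threshold_mode = "fixed", fixed_dab_threshold = 0.3)
  od2 <- matrix(0, 50, 50); od2[1:10, 1:10] <- 0.5
  expect_equal(sum(threshold_dab(od2, tis, fcfg)), 100)
  # pixels outside tissue are cleared
  tis2 <- tis; tis2[, 26:50] <- FALSE
  expect_equal(sum(threshold_dab(od, tis2, cfg) & !tis2), 0)
  # empty tissue: warning, not error
  expect_warning(m <- threshold_dab(od, matrix(FALSE, 50, 50), cfg),
                 "empty tissue")
  expect_equal(sum(m), 0)
})

test_that("outline closing seals gaps, is idempotent and extensive", {
  n <- 61; ctr <- 31
  d2 <- (row(matrix(0, n, n)) - ctr)^2 + (col(matrix(0, n, n)) - ctr)^2
  ring <- d2 <= 23^2 & d2 >= 20^2
  ang <- atan2(col(matrix(0, n, n)) - ctr, row(matrix(0, n, n)) - ctr)
  open_ring <- ring & !(abs(ang) < 2 / 23)     # ~4 px arc gap
  # open ring's complement is a single component; closing restores two
  expect_equal(max(EBImage::bwlabel((!open_ring) * 1)), 1)
  closed <- close_open_outlines(open_ring, 3, 1)
  expect_equal(max(EBImage::bwlabel((!closed) * 1)), 2)
  # idempotence
  expect_identical(close_open_outlines(closed, 3, 1), closed)
  # extensivity: closing never removes pixels
  expect_true(all(closed[open_ring]))
  # zero radius is the identity
  expect_identical(close_open_outlines(open_ring, 0, 1), open_ring)
  expect_identical(close_open_outlines(open_ring, 0.4, 1), open_ring)
  # two rings 30 px apart stay separate
  two <- matrix(FALSE, 61, 122)
  two[, 1:61] <- ring; two[, 62:122][ring] <- TRUE
  cl2 <- close_open_outlines(two, 3, 1)
  expect_equal(max(EBImage::bwlabel(cl2 * 1)), 2)
})

test_that("fill_and_label fills lumina, filters, labels 8-connected", {
  n <- 61; ctr <- 31
  d2 <- (row(matrix(0, n, n)) - ctr)^2 + (col(matrix(0, n, n)) - ctr)^2
  ring <- d2 <= 23^2 & d2 >= 20^2
  tis <- matrix(TRUE, n, n)
  regs <- fill_and_label(ring, 10, tis, 1)
  expect_length(regs, 1)
  expect_equal(regs[[1]]$area_px, pi * 23^2, tolerance = 0.03)
  expect_false(regs[[1]]$touches_border)
  expect_length(regs[[1]]$hole_contours, 1)
  # speck below min area is dropped
  speck <- matrix(FALSE, 20, 20); speck[10, 10:11] <- TRUE; speck[11, 10:11] <- TRUE
  expect_length(fill_and_label(speck, 10, matrix(TRUE, 20, 20), 1), 0)
  # two disjoint disks get distinct labels
  two <- matrix(FALSE, 40, 80)
  two[(row(two) - 20)^2 + (col(two) - 20)^2 <= 64] <- TRUE
  two[(row(two) - 20)^2 + (col(two) - 60)^2 <= 64] <- TRUE
  r2 <- fill_and_label(two, 10, matrix(TRUE, 40, 80), 1)
  expect_length(r2, 2)
  expect_setequal(vapply(r2, function(r) r$label, integer(1)), 1:2)
  # diagonal chain is one 8-connected region
  diagm <- matrix(FALSE, 12, 12)
  for (i in 1:8) diagm[i + 1, i + 1] <- TRUE
  for (i in 1:8) diagm[i + 1, i + 2] <- TRUE
  expect_length(fill_and_label(diagm, 0, matrix(TRUE, 12, 12), 1), 1)
  # border-touching region is flagged
  bar <- matrix(FALSE, 30, 30); bar[1:10, 5:25] <- TRUE
  expect_true(fill_and_label(bar, 0, matrix(TRUE, 30, 30), 1)[[1]]$touches_border)
})

test_that("stained mask is conserved through tissue masking and closing", {
  ph <- render_small_phantom(seed = 3)
  cfg_run <- run_config(microns_per_pixel = 0.5)
  seg <- segment_vessels(ph$tile, cfg_run)
  expect_true(all(seg$masks$tissue[seg$masks$stained]))
  expect_true(all(seg$masks$vessel[seg$masks$stained]))
  expect_gte(sum(seg$masks$vessel), sum(seg$masks$stained))
  expect_identical(dim(seg$masks$stained), dim(seg$masks$tissue))
})
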