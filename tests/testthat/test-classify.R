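test_that("caliber bands classify with half-open boundaries", {
  t <- segment_thresholds()
  expect_equal(as.character(classify_vessel(10, t)), "capillary")
  expect_equal(as.character(classify_vessel(30, t)), "sinusoid")
  # boundary belongs to the upper class
  expect_equal(as.character(classify_vessel(15, t)),
               "postcapillary_metarteriole")
  expect_equal(as.character(classify_vessel(20, t)), "sinusoid")
  expect_equal(as.character(classify_vessel(50, t)), "venule_arteriole")
  expect_equal(as.character(classify_vessel(100, t)), "vein_artery")
  expect_warning(cls <- classify_vessel(c(2, 10), t), "min_width")
  expect_true(is.na(cls[1]) && !is.na(cls[2]))
  expect_error(segment_thresholds(capillary_max = 25, postcap_max = 20))
})

test_that("every admissible width maps to exactly one class (partition)", {
  t <- segment_thresholds()
  set.seed(4)
  w <- runif(500, t$min_width, 150)
  cls <- classify_vessel(w, t)
  expect_false(anyNA(cls))
  expect_equal(sum(table(cls)), 500)
  # threshold monotonicity: raising capillary_max never loses capillaries
  n1 <- sum(classify_vessel(w, segment_thresholds(capillary_max = 12)) ==
              "capillary")
  n2 <- sum(classify_vessel(w, segment_thresholds(capillary_max = 15)) ==
              "capillary")
  expect_gte(n2, n1)
})

test_that("sample summary computes densities, SA and relative fractions", {
  masks <- structure(list(tissue = matrix(TRUE, 1000, 500),
                          stained = matrix(FALSE, 1000, 500)),
                     class = "mask_set")   # 0.5 mm^2 at 1 um/px
  v <- data.frame(label = 1:3, area_um2 = c(100, 200, 900),
                  length_um = c(12, 18, 40), width_um = c(10, 16, 30),
                  perimeter_um = c(40, 60, 110), aspect = c(1.2, 1.1, 1.3),
                  roundness = c(1.1, 1.2, 1.1),
                  perimeter_ratio = c(0.98, 0.97, 0.95),
                  deformity_um2 = c(1, 2, 10), shape_factor = c(0.01, 0.02, 0.05),
                  branch_count = c(0L, 0L, 1L),
                  touches_border = c(FALSE, FALSE, FALSE),
                  stained_px = c(2000, 3000, 5000))
  v$segment_class <- classify_vessel(v$width_um)
  s <- summarize_sample(v, masks, 1, "t1")
  expect_equal(s$sample$tissue_area_mm2, 0.5)
  expect_equal(s$sample$total_density, 6)         # 3 vessels / 0.5 mm^2
  expect_equal(s$sample$total_sa_percent, 2)      # 10000 / 500000 px
  expect_equal(sum(s$segments$relative_density), 100, tolerance = 0.01)
  expect_equal(sum(s$segments$density), s$sample$total_density)
  expect_equal(s$sample$capillary_relative_density, 100 / 3, tolerance = 1e-8)
  expect_error(summarize_sample(v, structure(list(
    tissue = matrix(FALSE, 10, 10)), class = "mask_set"), 1), "zero tissue")
})

test_that("relative densities follow segment counts (2 capillaries, 6 sinusoids)", {
  masks <- structure(list(tissue = matrix(TRUE, 100, 100)),
                     class = "mask_set")
  mk <- function(w) data.frame(label = 1, area_um2 = 50, length_um = w * 1.5,
                               width_um = w, perimeter_um = 30, aspect = 1.5,
                               roundness = 1.1, perimeter_ratio = 0.98,
                               deformity_um2 = 1, shape_factor = 0.01,
                               branch_count = 0L, touches_border = FALSE,
                               stained_px = 10)
  v <- do.call(rbind, c(lapply(rep(10, 2), mk), lapply(rep(30, 6), mk)))
  v$label <- seq_len(8)
  v$segment_class <- classify_vessel(v$width_um)
  s <- summarize_sample(v, masks, 1)
  seg <- s$segments
  expect_equal(seg$relative_density[seg$segment_class == "capillary"], 25)
  expect_equal(seg$relative_density[seg$segment_class == "sinusoid"], 75)
})

test_that("border-touching vessels count for density but not shape means", {
  masks <- structure(list(tissue = matrix(TRUE, 100, 100)),
                     class = "mask_set")
  v <- data.frame(label = 1:2, area_um2 = c(100, 500), length_um = c(12, 14),
                  width_um = c(10, 11), perimeter_um = c(40, 44),
                  aspect = c(1.2, 1.27), roundness = c(1.1, 1.15),
                  perimeter_ratio = c(0.99, 0.97), deformity_um2 = c(1, 3),
                  shape_factor = c(0.01, 0.03), branch_count = c(0L, 0L),
                  touches_border = c(FALSE, TRUE), stained_px = c(10, 20))
  v$segment_class <- classify_vessel(v$width_um)
  s <- summarize_sample(v, masks, 1)
  expect_equal(s$sample$n_vessels, 2)
  expect_equal(s$sample$mean_area_um2, 100)   # border vessel excluded
  s2 <- summarize_sample(v, masks, 1, exclude_border_from_shape = FALSE)
  expect_equal(s2$sample$mean_area_um2, 300)
})
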