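make_ci <- function(px, name = "test", um = 1) channel_image(px, name, um)

test_that("clip threshold mask matches the pixelwise comparison", {
  z <- make_ci(matrix(0, 8, 8))
  expect_equal(clip_threshold_mask(z, 10)$area_px, 0)
  u <- make_ci(matrix(50, 8, 8))
  expect_equal(clip_threshold_mask(u, 10)$area_px, 64)
  set.seed(1)
  px <- matrix(runif(400, 0, 100), 20)
  m <- clip_threshold_mask(make_ci(px), 37.5)
  expect_identical(m$mask, px > 37.5)
  expect_equal(m$area_um2, sum(px > 37.5))  # 1 um/px
})

test_that("adaptive threshold behaves on uniform, disk and noise images", {
  u <- make_ci(matrix(30, 64, 64))
  expect_equal(adaptive_threshold_mask(u, 11, offset = 1)$area_px, 0)

  # bright disk on flat background: disk pixels far exceed local mean
  px <- matrix(10, 64, 64)
  ctr <- 32
  for (i in 1:64) for (j in 1:64) {
    if ((i - ctr)^2 + (j - ctr)^2 <= 8^2) px[i, j] <- 200
  }
  m <- adaptive_threshold_mask(make_ci(px), 15, offset = 20)
  expect_true(m$mask[ctr, ctr])            # centroid inside mask
  inner <- px == 200 &
    outer((1:64 - ctr)^2, rep(1, 64)) + outer(rep(1, 64), (1:64 - ctr)^2) <= 4^2
  expect_true(all(m$mask[inner]))          # eroded interior fully covered

  # symmetric noise at offset 0 marks about half of the pixels
  set.seed(2)
  noise <- make_ci(matrix(pmax(rnorm(128^2, 100, 10), 0), 128))
  frac <- adaptive_threshold_mask(noise, 9, offset = 0)$area_px / 128^2
  expect_gt(frac, 0.45)
  expect_lt(frac, 0.55)

  expect_error(adaptive_threshold_mask(make_ci(matrix(1, 8, 8)), 100, 0),
               "parameter error")
})

test_that("adaptive local mean is exact against a direct window average", {
  set.seed(3)
  px <- matrix(runif(24 * 17, 0, 10), 24, 17)
  h <- 2
  m <- adaptive_threshold_mask(make_ci(px), window_um = 5, offset = 0.5)
  direct <- matrix(NA_real_, 24, 17)
  for (i in 1:24) for (j in 1:17) {
    direct[i, j] <- mean(px[max(1, i - h):min(24, i + h),
                            max(1, j - h):min(17, j + h)])
  }
  expect_identical(m$mask, px > direct + 0.5)
})

test_that("bleed-through subtraction zeroes only high-HLA-DR pixels", {
  pt <- make_ci(matrix(5, 6, 6), "ptdp43")
  lo <- make_ci(matrix(1, 6, 6), "hladr")
  hi <- make_ci(matrix(100, 6, 6), "hladr")
  expect_identical(subtract_bleedthrough(pt, lo, 50)$pixels, pt$pixels)
  expect_true(all(subtract_bleedthrough(pt, hi, 50)$pixels == 0))
  expect_error(subtract_bleedthrough(pt, make_ci(matrix(1, 3, 3)), 50),
               "input error")
})

test_that("master mask is a pixelwise union with algebraic mask properties", {
  set.seed(4)
  mk <- function() binary_mask(matrix(runif(100) > 0.6, 10), "x", "clip", 1)
  a <- mk(); b <- mk(); c <- mk()
  u <- master_mask(list(a, b))
  expect_identical(u$mask, a$mask | b$mask)           # OR oracle
  expect_identical(master_mask(list(a, a))$mask, a$mask)  # idempotent
  expect_identical(master_mask(list(b, a))$mask, u$mask)  # commutative
  expect_identical(master_mask(list(master_mask(list(a, b)), c))$mask,
                   master_mask(list(a, master_mask(list(b, c))))$mask)
  expect_lte(u$area_px, a$area_px + b$area_px)
  # disjoint masks add exactly
  d1 <- matrix(FALSE, 10, 10); d1[1:2, ] <- TRUE
  d2 <- matrix(FALSE, 10, 10); d2[5:6, 1:5] <- TRUE
  expect_equal(master_mask(list(binary_mask(d1, "a", "clip", 1),
                                binary_mask(d2, "b", "clip", 1)))$area_px, 30)
})

test_that("label_objects finds 8-connected components above the area cutoff", {
  empty <- matrix(FALSE, 10, 10)
  expect_equal(nrow(label_objects(empty, min_area_px = 1)$objects), 0)

  two <- matrix(FALSE, 20, 20)
  two[2:6, 2:6] <- TRUE; two[10:14, 10:14] <- TRUE
  lab <- label_objects(two, min_area_px = 1)
  expect_equal(nrow(lab$objects), 2)
  expect_equal(lab$objects$area_px, c(25, 25))
  # centroids are 0-based (row, col)
  expect_equal(lab$objects$row, c(3, 11))

  # diagonal-only touch is one object under 8-connectivity
  diagm <- matrix(FALSE, 5, 5); diagm[1, 1] <- TRUE; diagm[2, 2] <- TRUE
  expect_equal(nrow(label_objects(diagm, min_area_px = 1)$objects), 1)

  # min-area filter discards fragments
  frag <- two; frag[18, 18] <- TRUE
  expect_equal(nrow(label_objects(frag, min_area_px = 5)$objects), 2)

  # object count is translation invariant away from borders
  set.seed(5)
  blob <- matrix(runif(64) > 0.5, 8)
  big <- matrix(FALSE, 40, 40); big[5:12, 5:12] <- blob
  shifted <- matrix(FALSE, 40, 40); shifted[20:27, 14:21] <- blob
  expect_equal(nrow(label_objects(big, min_area_px = 1)$objects),
               nrow(label_objects(shifted, min_area_px = 1)$objects))
})

test_that("measure_cells averages intensities over object pixels", {
  labmask <- matrix(FALSE, 10, 10); labmask[2:4, 2:4] <- TRUE
  lab <- label_objects(labmask, min_area_px = 1)
  ch <- matrix(7, 10, 10); ch[2:4, 2:4] <- 200
  ims <- multiplex_image_set(
    setNames(lapply(GLIAMUX_MARKERS, function(m) ch), GLIAMUX_MARKERS),
    roi = matrix(TRUE, 10, 10),
    meta = list(case_id = "t1", group = "control", region = "motor_cortex"),
    um_per_px = 1)
  cells <- measure_cells(lab, ims)
  expect_equal(nrow(cells), 1)
  expect_equal(cells$cd68, 200)
  # equal thirds of {10, 20, 30} average to 20
  ch2 <- matrix(0, 10, 10); ch2[2:4, 2] <- 10; ch2[2:4, 3] <- 20
  ch2[2:4, 4] <- 30
  ims2 <- multiplex_image_set(list(cd68 = ch2), matrix(TRUE, 10, 10),
                              meta = list(case_id = "t2"), um_per_px = 1)
  expect_equal(measure_cells(lab, ims2, markers = "cd68")$cd68, 20)
  expect_error(measure_cells(lab, ims2, markers = "neun"), "input error")
})

test_that("load measures are exact on constructed inputs and linear", {
  roi <- matrix(FALSE, 40, 40); roi[4:36, 4:36] <- TRUE  # not full field
  img <- matrix(0, 40, 40); img[10:11, 10:14] <- 100     # 10 px at 100
  ci <- make_ci(img, "ptdp43")
  mask <- clip_threshold_mask(ci, 50)
  expect_equal(pathology_load(ci, mask, roi), 1000 / sum(roi))
  expect_equal(pathology_load(make_ci(matrix(0, 40, 40)), mask, roi), 0)
  # linear in intensity
  expect_equal(pathology_load(make_ci(2 * img, "x"), mask, roi),
               2 * pathology_load(ci, mask, roi))
  # content outside the ROI is ignored
  img2 <- img; img2[1, 1] <- 1e6
  m2 <- clip_threshold_mask(make_ci(img2), 50)
  expect_equal(pathology_load(make_ci(img2), m2, roi),
               pathology_load(ci, mask, roi))
  expect_error(pathology_load(ci, mask, matrix(FALSE, 40, 40)),
               "input error.*ROI")
})

test_that("area load and cell density follow their definitions", {
  roi <- matrix(TRUE, 20, 20)
  full <- binary_mask(roi, "gfap", "clip", 1)
  expect_equal(area_load(full, roi), 1)
  expect_equal(area_load(matrix(FALSE, 20, 20), roi), 0)
  half <- matrix(FALSE, 20, 20); half[1:10, ] <- TRUE
  expect_equal(area_load(half, roi), 0.5)
  # 50 cells in exactly 1 mm^2 (1000 x 1000 px at 1 um/px)
  roi_mm <- matrix(TRUE, 1000, 1000)
  expect_equal(cell_density(50, roi_mm, 1), 50)
  expect_equal(cell_density(data.frame()[0, ], roi_mm, 1), 0)
})

test_that("tissue-wide intensity supports both normalisations", {
  roi <- matrix(TRUE, 20, 20)
  mask <- matrix(FALSE, 20, 20); mask[1:5, 1:8] <- TRUE  # 40 px
  img <- make_ci(matrix(3, 20, 20))
  bm <- binary_mask(mask, "cd68", "clip", 1)
  expect_equal(tissue_wide_intensity(img, bm, roi), 3 * 40 / 400)
  expect_equal(tissue_wide_intensity(img, bm, roi, normalise = "mask"), 3)
  expect_equal(tissue_wide_intensity(img,
                                     binary_mask(matrix(FALSE, 20, 20),
                                                 "cd68", "clip", 1), roi), 0)
  expect_equal(tissue_wide_intensity(make_ci(2 * img$pixels, "x"), bm, roi),
               2 * tissue_wide_intensity(img, bm, roi))
})
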