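# ROI fluorescence quantification.

square_roi <- function(r0, r1, c0, c1, psz = 1) {
  # half-offset vertices keep pixel centres strictly inside the polygon
  roi(rbind(
    c(r0 - 0.45, c0 - 0.45), c(r0 - 0.45, c1 + 0.45),
    c(r1 + 0.45, c1 + 0.45), c(r1 + 0.45, c0 - 0.45)
  ), pixel_size_um = psz)
}

test_that("mean intensity is the arithmetic mean over included pixel centres", {
  img <- matrix(7, 30, 30)
  expect_equal(roi_mean_intensity(img, square_roi(5, 20, 5, 20)), 7)

  img2 <- matrix(0, 30, 30)
  img2[, 16:30] <- 10
  expect_equal(roi_mean_intensity(img2, square_roi(1, 30, 1, 30)), 5)
})

test_that("degenerate and out-of-bounds ROIs error", {
  img <- matrix(1, 20, 20)
  expect_error(roi(rbind(c(1, 1), c(5, 5)), 1), "n >= 3")
  expect_error(
    roi_mean_intensity(img, square_roi(5, 30, 5, 10)),
    "bounds"
  )
  # self-intersecting bow-tie
  expect_error(
    roi(rbind(c(1, 1), c(10, 10), c(1, 10), c(10, 1)), 1),
    "self-intersect"
  )
})

test_that("fold change against the negative control follows its definition", {
  expect_equal(fold_change_vs_negative(30, 10), 3)
  expect_equal(fold_change_vs_negative(10, 10), 1)
  expect_error(fold_change_vs_negative(30, 0), ">")
})

test_that("gray value is the ROI total normalized to 10,000 um^2", {
  # 50 x 40 px at 10 um/px: 2000 px = 200,000 um^2; value 1 -> sum 2000
  img <- matrix(1, 50, 40)
  r <- square_roi(1, 50, 1, 40, psz = 10)
  expect_equal(gray_per_area(img, r), 2000 / 2e5 * 1e4)
  # identity normalization at exactly 10,000 um^2 (10 x 10 px at 10 um/px)
  r2 <- square_roi(1, 10, 1, 10, psz = 10)
  img3 <- matrix(5, 50, 40)
  expect_equal(gray_per_area(img3, r2), 5 * 100)
  expect_equal(gray_per_area(img3, r2, mode = "mean"), 5 / 1e4 * 1e4)
})

test_that("gray per area recombines additively over a split ROI", {
  set.seed(8)
  img <- matrix(sample(0:255, 40 * 40, TRUE), 40, 40)
  whole <- square_roi(5, 24, 5, 34, psz = 2)
  left <- square_roi(5, 24, 5, 19, psz = 2)
  right <- square_roi(5, 24, 20, 34, psz = 2)
  a_l <- 20 * 15 * 4
  a_r <- 20 * 15 * 4
  recombined <- (gray_per_area(img, left) * a_l + gray_per_area(img, right) * a_r) /
    (a_l + a_r)
  expect_equal(gray_per_area(img, whole), recombined, tolerance = 1e-12)
})

test_that("mean intensity is invariant under joint translation", {
  set.seed(9)
  img <- matrix(sample(0:255, 50 * 50, TRUE), 50, 50)
  shifted <- matrix(0, 50, 50)
  shifted[6:50, 4:50] <- img[1:45, 1:47]
  r0 <- roi(rbind(c(2.6, 2.6), c(2.6, 20.4), c(25.4, 12.3)), 1)
  r1 <- roi(rbind(c(7.6, 5.6), c(7.6, 23.4), c(30.4, 15.3)), 1)
  expect_equal(roi_mean_intensity(img, r0), roi_mean_intensity(shifted, r1))
})

test_that("quantify_rois returns one tidy row per region", {
  img <- matrix(10, 30, 30)
  img[10:20, 10:20] <- 50
  rois <- list(square_roi(10, 20, 10, 20), square_roi(1, 5, 1, 5))
  out <- quantify_rois(img, rois, negative_mean_fi = 10)
  expect_equal(nrow(out), 2L)
  expect_equal(out$mean_fi, c(50, 10))
  expect_equal(out$fold_change, c(5, 1))
})
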