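test_that("area resize averages exact source regions", {
  # one bright 2x2 quadrant in a 4x4 image, factor 0.5: each output pixel is
  # the mean of its 2x2 block
  img <- flat_rgb(4, 4, c(0, 0, 0))
  img[1:2, 1:2, ] <- 200
  out <- resize_region(img, 0.5)
  expect_equal(dim(out), c(2L, 2L, 3L))
  expect_equal(out[1, 1, 1], 200)
  expect_equal(out[1, 2, 1], 0)
  expect_equal(out[2, 2, 3], 0)

  # constant image stays constant at scaled extents
  const <- flat_rgb(20, 30, c(57, 120, 3))
  out2 <- resize_region(const, 0.4)
  expect_equal(dim(out2), c(8L, 12L, 3L))
  expect_true(all(abs(out2[, , 1] - 57) < 1e-9))

  # extents use round-to-nearest: 51 * 0.2 -> 10, 42 * 0.2 -> 8
  out3 <- resize_region(flat_rgb(51, 42, c(9, 9, 9)), 0.2)
  expect_equal(dim(out3)[1:2], c(10L, 8L))

  # fractional-overlap weights: 3 rows -> 2 rows averages with weights 1, 1/2
  img4 <- flat_rgb(9, 9, c(0, 0, 0))
  img4[1:3, , 1] <- c(30, 60, 90)   # rows 1..3 per column
  out4 <- resize_region(img4, 1 / 3)
  expect_equal(out4[1, 1, 1], mean(c(30, 60, 90)))

  expect_error(resize_region(flat_rgb(20, 20, c(1, 1, 1)), 0.05),
               class = "tubershape_size_error")
  expect_error(resize_region(flat_rgb(20, 20, c(1, 1, 1)), 1.5),
               class = "tubershape_arg_error")
})

test_that("graying uses the conventional luma weights", {
  expect_true(all(to_gray(flat_rgb(8, 8, c(255, 255, 255))) == 255))
  expect_true(all(to_gray(flat_rgb(8, 8, c(0, 0, 0))) == 0))
  expect_equal(to_gray(flat_rgb(8, 8, c(255, 0, 0)))[1, 1], 76)
  expect_equal(to_gray(flat_rgb(8, 8, c(0, 255, 0)))[1, 1], round(0.587 * 255))
})

test_that("Otsu segmentation separates bimodal intensities", {
  gray <- matrix(0, 10, 10)
  gray[, 6:10] <- 255
  res <- otsu_binarize(gray)
  expect_identical(res$mask, gray == 255)
  expect_true(res$threshold > 0 && res$threshold < 255)

  expect_error(otsu_binarize(matrix(128, 10, 10)),
               class = "tubershape_contrast_error")

  # noisy bright ellipse on dark field agrees with the analytic truth mask
  spec <- shape_spec(a = 100, b = 60, theta = 0.7, seed = 42,
                     boundary_jitter = 0)
  s <- render_sample(spec)
  seg <- otsu_binarize(to_gray(s$image))
  expect_gt(mean(seg$mask == s$truth_mask), 0.99)

  # dark polarity flips the foreground
  inv <- otsu_binarize(255 - to_gray(s$image), polarity = "dark")
  expect_gt(mean(inv$mask == s$truth_mask), 0.99)
})

test_that("morphological cleanup removes specks, fills pinholes, matches set algebra", {
  mask <- matrix(FALSE, 40, 40)
  mask[10:30, 10:30] <- TRUE
  mask[18, 18] <- FALSE               # interior pinhole
  speckled <- mask
  speckled[cbind(c(3, 5, 36), c(4, 37, 2))] <- TRUE  # isolated specks
  out <- morphological_clean(speckled, kernel_radius = 2)
  expect_false(any(out[cbind(c(3, 5, 36), c(4, 37, 2))]))
  expect_true(out[18, 18])            # pinhole closed
  expect_true(all(out[12:28, 12:28]))

  # opening then closing equals the erode/dilate/dilate/erode oracle
  blob <- disc_mask(30, 30, 14, 15, 8)
  blob[4, 4] <- TRUE
  se <- as.matrix(EBImage::makeBrush(5, "disc"))
  oracle <- brute_erode(brute_dilate(brute_dilate(brute_erode(blob, se), se), se), se)
  expect_identical(morphological_clean(blob, 2), oracle)

  lone <- matrix(FALSE, 20, 20)
  lone[5, 5] <- TRUE                  # opening wipes a sub-element speck
  expect_error(morphological_clean(lone, kernel_radius = 2),
               class = "tubershape_empty_mask_error")
})

test_that("majority smoothing matches the windowed-majority oracle", {
  all_fg <- matrix(TRUE, 15, 15)
  expect_identical(median_smooth(all_fg, 3), all_fg)

  lone <- matrix(FALSE, 15, 15)
  lone[8, 8] <- TRUE
  expect_false(any(median_smooth(lone, 3)))

  # jagged staircase edge of a disc, window 5: exact oracle equality
  jag <- disc_mask(40, 40, 20, 19, 13)
  set.seed(5)
  edge <- which(jag & !brute_erode(jag, matrix(1, 3, 3)))
  jag[sample(edge, 20)] <- FALSE      # roughen the boundary
  expect_identical(median_smooth(jag, 5), brute_majority(jag, 5L))
  # and window-3 equality on the same mask
  expect_identical(median_smooth(jag, 3), brute_majority(jag, 3L))

  expect_error(median_smooth(all_fg, 4))
})

test_that("centering moves the centroid to the canvas center and preserves mass", {
  mask <- matrix(FALSE, 100, 100)
  mask[6:15, 6:15] <- TRUE            # centroid (10.5, 10.5) 0-based
  out <- center_translate(mask)
  xy <- which(out, arr.ind = TRUE)
  centroid <- c(mean(xy[, 2]) - 1, mean(xy[, 1]) - 1)
  expect_lt(max(abs(centroid - c(49.5, 49.5))), 1)
  expect_identical(sum(out), sum(mask))

  centered <- center_translate(out)
  expect_identical(centered, out)     # already centered: zero shift

  wide <- matrix(FALSE, 20, 20)
  wide[9:11, ] <- TRUE
  expect_error(center_translate(wide),
               class = "tubershape_object_too_large_error")
  expect_error(center_translate(matrix(FALSE, 10, 10)),
               class = "tubershape_empty_mask_error")
})

test_that("full pipeline turns a large capture into a clean centered mask", {
  # nominal-resolution capture downscales to the 614 x 410 working extents
  spec <- shape_spec(a = 480, b = 330, theta = 0.3, center = c(1500, 1000),
                     seed = 9, boundary_jitter = 2)
  s <- render_sample(spec, extents = c(width = 3072, height = 2048))
  mask <- preprocess_pipeline(s$image)
  expect_equal(dim(mask), c(410L, 614L))
  lab <- EBImage::bwlabel(EBImage::Image(t(mask) * 1))
  expect_equal(max(lab), 1)           # a single connected component
  expect_gt(sum(mask), 0)

  # determinism: identical input gives an identical mask
  expect_identical(preprocess_pipeline(s$image), mask)

  # an all-dark frame fails in the Otsu stage, with the stage identified
  err <- tryCatch(preprocess_pipeline(flat_rgb(64, 96, c(12, 12, 12))),
                  error = identity)
  expect_s3_class(err, "tubershape_stage_error")
  expect_identical(err$stage, "otsu")

  # input already at reference extents skips resizing (identity stage)
  s2 <- render_sample(shape_spec(a = 100, b = 65, seed = 10))
  m2 <- preprocess_pipeline(s2$image)
  expect_gt(mean(m2 == s2$truth_mask), 0.99)
})

test_that("cleanup stages are near-idempotent and preprocessing matches truth", {
  s <- render_sample(shape_spec(a = 120, b = 75, theta = 1.1, seed = 21))
  mask <- preprocess_pipeline(s$image)
  expect_gt(mean(mask == s$truth_mask), 0.99)

  m1 <- morphological_clean(mask, 2)
  expect_lt(mean(m1 != morphological_clean(m1, 2)), 0.005)
  m2 <- median_smooth(mask, 5)
  expect_lt(mean(m2 != median_smooth(m2, 5)), 0.005)
})
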