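test_that("binarize uses a strict inequality and supports inversion", {
  X <- matrix(c(10L, 200L, 128L, 129L), 2, 2, byrow = TRUE)
  expect_identical(binarize(X, 128),
                   matrix(c(0L, 1L, 0L, 1L), 2, 2, byrow = TRUE))
  expect_identical(binarize(matrix(0L, 3, 3), 0), matrix(0L, 3, 3))  # 0 > 0 is false
  eq <- matrix(100L, 2, 2)
  expect_identical(binarize(eq, 100, invert = FALSE), matrix(0L, 2, 2))
  expect_identical(binarize(eq, 100, invert = TRUE), matrix(1L, 2, 2))
  expect_error(binarize(eq, 300), "\\[0, 255\\]")
})

test_that("Otsu threshold matches the exhaustive-scan oracle", {
  set.seed(21)
  for (rep in 1:10) {
    X <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    T_got <- otsu_threshold(X)
    T_oracle <- naive_otsu(X)
    expect_identical(T_got, T_oracle)
  }
  # two-level image: binarizing at the returned T recovers the upper class
  X2 <- matrix(sample(c(50L, 200L), 100, replace = TRUE), 10, 10)
  T2 <- otsu_threshold(X2)
  expect_identical(binarize(X2, T2), matrix(as.integer(X2 == 200L), 10, 10))
  # half 0 / half 255: every split ties, smallest threshold wins
  X3 <- matrix(c(rep(0L, 8), rep(255L, 8)), 4, 4)
  expect_identical(otsu_threshold(X3), 0L)
  expect_identical(binarize(X3, otsu_threshold(X3)),
                   matrix(as.integer(X3 == 255L), 4, 4))
  expect_error(otsu_threshold(matrix(7L, 3, 3)), "constant")
})

test_that("automatic ROI keeps the k largest components with stable ties", {
  m <- matrix(0L, 20, 30)
  m[2:11, 2:11] <- 1L          # area 100
  m[2:10, 15:24] <- 1L         # area 90
  m[18, 1:5] <- 1L             # area 5
  q <- make_roi_mask(m, seg_config(roi_k = 2))
  expect_identical(sum(q), 190L)
  expect_identical(q[18, 3], 0L)
  # roi_k larger than the number of components saturates to the union
  expect_identical(make_roi_mask(m, seg_config(roi_k = 10)), m)
  expect_error(make_roi_mask(matrix(0L, 4, 4), seg_config()), "no candidate")
  # equal areas: the first-encountered (row-major) component wins
  tie <- matrix(0L, 6, 6); tie[1, 5:6] <- 1L; tie[5, 1:2] <- 1L
  q1 <- make_roi_mask(tie, seg_config(roi_k = 1))
  expect_identical(q1[1, 5], 1L)
  expect_identical(sum(q1), 2L)
})

test_that("external ROI files are loaded and dimension-checked", {
  roi_path <- withr::local_tempfile(fileext = ".png")
  roi <- matrix(0L, 6, 6); roi[2:5, 2:5] <- 1L
  write_mask(roi, roi_path)
  cfg <- seg_config(roi_policy = "external_file", roi_path = roi_path)
  W <- matrix(1L, 6, 6)
  expect_identical(make_roi_mask(W, cfg), roi)
  expect_error(make_roi_mask(matrix(1L, 4, 4), cfg), "dimension")
  expect_error(seg_config(roi_policy = "external_file"), "roi_path")
})

test_that("mask application is an element-wise AND", {
  W <- matrix(c(1L, 1L, 0L, 1L), 2, 2, byrow = TRUE)
  Q <- matrix(c(1L, 0L, 1L, 1L), 2, 2, byrow = TRUE)
  got <- apply_mask(W, Q)
  expect_identical(got, matrix(c(1L, 0L, 0L, 1L), 2, 2, byrow = TRUE))
  expect_true(subset_mask(got, W) && subset_mask(got, Q))
  expect_identical(apply_mask(W, matrix(1L, 2, 2)), W)
  expect_identical(apply_mask(W, matrix(0L, 2, 2)), matrix(0L, 2, 2))
  expect_error(apply_mask(W, matrix(1L, 3, 3)), "dimension")
})

test_that("overlay blends the colour at weight 0.5 over the mask", {
  X <- matrix(100L, 2, 2)
  mask <- matrix(c(1L, 0L, 0L, 0L), 2, 2)
  ov <- overlay_image(X, mask, color = c(255L, 0L, 0L))
  expect_identical(ov[1, 1, ], c(178L, 50L, 50L))   # round(0.5*100 + 0.5*c)
  expect_identical(ov[2, 2, ], c(100L, 100L, 100L)) # plain grayscale outside
  # all-ones mask: the product image equals X itself
  res_all <- X * matrix(1L, 2, 2)
  expect_identical(res_all, X)
  expect_error(overlay_image(X, matrix(1L, 3, 3)), "dimension")
  expect_error(overlay_image(X, mask, color = c(-1, 0, 0)), "RGB")
})

test_that("the composed pipeline keeps its stage invariants", {
  ph <- make_phantom(grade_default_spec(1, seed = 4))
  res <- segment(ph$image)
  expect_s3_class(res, "seg_result")
  # closed mask never leaks outside the ROI
  expect_true(subset_mask(res$closed, res$roi))
  expect_true(subset_mask(res$masked, res$cleaned))
  # product image is the radiograph restricted to the closed mask
  expect_identical(res$product, ph$image * res$closed)
  # deterministic: same input and config give a bit-identical result
  res2 <- segment(ph$image)
  expect_identical(res, res2)
  # stage logging names each stage with its foreground count
  expect_message(segment(ph$image, verbose = TRUE), "stage=binarize")
})

test_that("degenerate inputs are handled per contract", {
  flat <- matrix(128L, 16, 16)
  expect_error(segment(flat), "constant")
  # fixed threshold at mid-gray on a uniform image: every stage empty,
  # so no ROI candidate exists
  cfg <- seg_config(threshold_mode = "fixed", threshold_value = 100,
                    invert_polarity = TRUE)
  expect_error(segment(flat, cfg), "no candidate")
  expect_identical(binarize(flat, 100, invert = TRUE), matrix(0L, 16, 16))
})
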