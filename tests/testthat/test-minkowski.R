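test_that("thresholding keeps pixels at or above the level", {
  img <- as_gray(matrix(c(10, 200, 128, 255), 2, 2, byrow = TRUE))
  expect_true(all(threshold_level_set(img, 0)))       # every value >= 0
  expect_false(any(threshold_level_set(as_gray(matrix(200, 2, 2)), 201)))
  expect_equal(sum(threshold_level_set(img, 128)), 3L)
  expect_error(threshold_level_set(img, 256), "255")
  expect_error(threshold_level_set(img, -1), "255")
})

test_that("area counts foreground pixels", {
  expect_equal(area(matrix(FALSE, 4, 4)), 0L)
  expect_equal(area(matrix(TRUE, 512, 512)), 262144L)
  set.seed(3)
  m <- rand_mask(16, 16, 0.4)
  expect_equal(area(m), sum(as.integer(m)))
})

test_that("contour length counts exposed pixel edges, exterior = background", {
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  expect_equal(contour_length(m), 4L)

  sq <- matrix(FALSE, 7, 7); sq[3:5, 3:5] <- TRUE
  expect_equal(contour_length(sq), 12L)

  # border pixels contribute their outward edges
  expect_equal(contour_length(matrix(TRUE, 4, 6)), 20L)

  set.seed(13)
  for (i in 1:200) {
    m <- rand_mask(16, 16, sample(c(0.2, 0.5, 0.8), 1L))
    expect_equal(contour_length(m), oracle_contour(m))
  }
})

test_that("two objects jointly enclosing four holes give chi = -2", {
  expect_equal(euler_characteristic(two_objects_four_holes_mask()), -2L)
})

test_that("degenerate masks have the expected Euler characteristic", {
  expect_equal(euler_characteristic(matrix(TRUE, 6, 9)), 1L)
  expect_equal(euler_characteristic(matrix(FALSE, 6, 9)), 0L)
})

test_that("quad counting equals the labeling oracle on all 3x3 images", {
  for (m in all_3x3_masks()) {
    expect_equal(euler_characteristic(m), oracle_euler(m))
  }
})

test_that("quad counting equals the labeling oracle on random masks", {
  set.seed(17)
  for (p in c(0.2, 0.5, 0.8)) {
    for (i in 1:60) {
      m <- rand_mask(32, 32, p)
      expect_equal(euler_characteristic(m), oracle_euler(m))
    }
  }
})

test_that("functionals are additive over well-separated sub-masks", {
  set.seed(23)
  for (i in 1:50) {
    a <- rand_mask(8, 8, 0.5)
    b <- rand_mask(8, 8, 0.5)
    combined <- matrix(FALSE, 8, 20)
    combined[, 1:8] <- a
    combined[, 13:20] <- b
    expect_equal(area(combined), area(a) + area(b))
    expect_equal(contour_length(combined), contour_length(a) + contour_length(b))
    expect_equal(euler_characteristic(combined),
                 euler_characteristic(a) + euler_characteristic(b))
  }
})

test_that("a filled rectangle with k isolated holes has chi = 1 - k", {
  holes <- cbind(c(3, 3, 6, 6, 9, 9), c(3, 7, 5, 9, 3, 7))
  for (k in 0:6) {
    m <- matrix(FALSE, 12, 12)
    m[2:10, 2:10] <- TRUE
    if (k > 0) m[holes[seq_len(k), , drop = FALSE]] <- FALSE
    expect_equal(euler_characteristic(m), 1L - k)
  }
})

test_that("curve sweep equals per-level recomputation", {
  imgs <- list(
    gradient = as_gray(matrix(rep(0:7 * 36, each = 8), 8, 8, byrow = FALSE)),
    random = {
      set.seed(29)
      as_gray(matrix(sample(0:255, 24 * 24, TRUE), 24, 24))
    },
    few_levels = {
      set.seed(37)
      as_gray(matrix(sample(c(0, 17, 130, 255), 16 * 16, TRUE), 16, 16))
    })
  for (img in imgs) {
    cv <- minkowski_curves(img, "x")
    for (t in 0:255) {
      b <- threshold_level_set(img, t)
      expect_equal(cv$area[t + 1], area(b))
      expect_equal(cv$contour_length[t + 1], contour_length(b))
      expect_equal(cv$euler[t + 1], euler_characteristic(b))
    }
  }
})

test_that("constant images give single-step curves", {
  g <- 97L
  img <- matrix(g, 10, 14)
  cv <- minkowski_curves(img, "const")
  expect_equal(cv$euler, c(rep(1, g + 1), rep(0, 255 - g)))
  expect_equal(cv$area, c(rep(140, g + 1), rep(0, 255 - g)))
})

test_that("curve invariants hold on random gray images", {
  set.seed(41)
  for (i in 1:20) {
    img <- as_gray(matrix(sample(0:255, 16 * 16, TRUE), 16, 16))
    cv <- minkowski_curves(img, "x")
    expect_true(all(diff(cv$area) <= 0))
    expect_equal(cv$area[1], 256)
    expect_equal(cv$euler[1], 1)
    expect_equal(cv$contour_length[1], 2 * (16 + 16))
    # top-level set: chi equals its component count; with at most one pixel
    # at level 255 that is 0 or 1
    if (sum(img == 255L) <= 1L) expect_true(cv$euler[256] %in% c(0, 1))
  }
})

test_that("a fibrous grade-II-like texture yields a sigmoid Euler curve", {
  p <- texture_params("gradeII", image_size = 128, seed = 5)
  g <- equalize_histogram(flatten_first_order(generate_tissue_image(p)))
  cv <- minkowski_curves(g, "gII")
  expect_lt(min(cv$euler), 0)
  expect_gt(max(cv$euler), 0)
  expect_lt(which.min(cv$euler), which.max(cv$euler))  # dip before bump
})
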