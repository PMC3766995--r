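test_that("degenerate all-zero curves give all-zero descriptors", {
  f <- extract_features(make_curve())
  expect_equal(unname(f), rep(0, 15))
  expect_named(f, feature_names())
})

test_that("triangular contour peak matches closed-form descriptors", {
  tri <- piecewise_curve(c(0, 128, 255), c(0, 100, 0))
  cv <- make_curve(contour = tri)
  f <- extract_features(cv)
  expect_equal(unname(f["contour_max"]), 100)
  expect_equal(unname(f["contour_argmax"]), 128)
  # direct-sum oracle on the discrete triangle
  at_half <- which(tri >= 50)
  expect_equal(unname(f["contour_fwhm"]), max(at_half) - min(at_half))
  expect_equal(unname(f["contour_area"]), sum(tri))
  expect_equal(unname(f["contour_centroid"]), sum((0:255) * tri) / sum(tri))
})

test_that("euler extremum descriptors recover constructed extremes", {
  e <- piecewise_curve(c(0, 46, 150, 210, 255), c(0, -905, 0, 341, 0))
  f <- extract_features(make_curve(euler = e))
  expect_equal(unname(f["euler_min"]), -905)
  expect_equal(unname(f["euler_argmin"]), 46)
  expect_equal(unname(f["euler_max"]), 341)
  expect_equal(unname(f["euler_argmax"]), 210)
  expect_equal(unname(f["euler_zero_cross"]), 150)
  expect_equal(unname(f["euler_area_neg"]), sum(pmin(e, 0)))
  expect_equal(unname(f["euler_area_pos"]), sum(pmax(e, 0)))
  expect_equal(unname(f["euler_area_total"]), sum(e))
})

test_that("extremum ties resolve to the lowest gray level", {
  e <- rep(c(-3, 5), each = 128)
  f <- extract_features(make_curve(euler = e))
  expect_equal(unname(f["euler_argmin"]), 0)
  expect_equal(unname(f["euler_argmax"]), 128)
})

test_that("missing zero-crossing saturates at 255", {
  e <- piecewise_curve(c(0, 100, 255), c(-1, -500, -2))  # never back to >= 0
  f <- extract_features(make_curve(euler = e))
  expect_equal(unname(f["euler_zero_cross"]), 255)
})

test_that("descriptors are scale-consistent in the euler curve", {
  set.seed(43)
  e <- cumsum(rnorm(256))
  base <- extract_features(make_curve(euler = e))
  scaled_feats <- c("euler_min", "euler_max", "euler_max_slope",
                    "euler_area_neg", "euler_area_pos", "euler_area_total")
  fixed_feats <- c("euler_argmin", "euler_argmax", "euler_zero_cross",
                   "euler_max_slope_pos")
  for (lambda in c(0.5, 2, 7)) {
    f <- extract_features(make_curve(euler = lambda * e))
    expect_equal(f[scaled_feats], lambda * base[scaled_feats])
    expect_equal(f[fixed_feats], base[fixed_feats])
  }
})

test_that("group statistics follow mean and sample-sd definitions", {
  set.seed(47)
  base <- cumsum(rnorm(256))
  cv <- make_curve(euler = base, contour = abs(base))

  same <- group_stats(list(cv, cv, cv), "g")
  expect_equal(same$euler_mean, base)
  expect_true(all(same$euler_sd == 0))

  opposite <- group_stats(list(make_curve(euler = base),
                               make_curve(euler = -base)), "g")
  expect_equal(opposite$euler_mean, rep(0, 256))

  expect_error(group_stats(list(cv), "g"), "at least 2")
})

test_that("per-level sd of unit-normal noise is near 1 at n = 10", {
  set.seed(53)
  base <- piecewise_curve(c(0, 128, 255), c(0, -400, 100))
  curves <- lapply(1:10, function(i) make_curve(euler = base + rnorm(256)))
  g <- group_stats(curves, "g")
  expect_gte(mean(g$euler_sd >= 0.5 & g$euler_sd <= 1.5), 0.95)
})

test_that("mean of two equal-size group means equals the pooled mean", {
  set.seed(59)
  mk <- function() make_curve(euler = rnorm(256))
  g1 <- lapply(1:6, function(i) mk())
  g2 <- lapply(1:6, function(i) mk())
  pooled <- group_stats(c(g1, g2), "all")
  expect_equal(pooled$euler_mean,
               (group_stats(g1, "a")$euler_mean +
                group_stats(g2, "b")$euler_mean) / 2)
})

test_that("extreme-value ratios reproduce the reference ratios", {
  mk_group <- function(minv, maxv) {
    e <- piecewise_curve(c(0, 40, 140, 210, 255), c(0, minv, 0, maxv, 0))
    group_stats(list(make_curve("a", euler = e), make_curve("b", euler = e)),
                "g")
  }
  astro <- mk_group(-905, 341)
  glio <- mk_group(-582, 238)
  r <- compare_group_extremes(astro, glio)
  expect_equal(r$report$min_ratio, 1.55)
  expect_equal(r$report$max_ratio, 1.43)
  expect_false(r$undefined)

  same <- compare_group_extremes(astro, astro)
  expect_equal(same$report$min_ratio, 1)
  expect_equal(same$report$max_ratio, 1)
})

test_that("zero-valued denominator extremes raise the undefined flag", {
  flat <- group_stats(list(make_curve(euler = rep(0, 256)),
                           make_curve(euler = rep(0, 256))), "flat")
  bumpy_curve <- make_curve(euler = piecewise_curve(c(0, 128, 255),
                                                    c(0, -10, 5)))
  bumpy <- group_stats(list(bumpy_curve, bumpy_curve), "b")
  r <- compare_group_extremes(bumpy, flat)
  expect_true(r$undefined)
  expect_true(is.na(r$min_ratio))
})

test_that("non-overlap bands are found exactly where 1-sigma bands separate", {
  mk <- function(mean_curve, sd_val) {
    curves <- list(make_curve(euler = mean_curve - sd_val),
                   make_curve(euler = mean_curve + sd_val))
    group_stats(curves, "g")   # sample sd of {m-s, m+s} is s * sqrt(2)
  }
  g_hi <- mk(rep(10, 256), 0.1)
  g_lo <- mk(rep(0, 256), 0.1)
  band <- find_nonoverlap_band(g_hi, g_lo)
  expect_equal(band, data.frame(start = 0L, end = 255L))

  expect_equal(nrow(find_nonoverlap_band(g_hi, g_hi)), 0L)

  # separated only between gray levels 80 and 105
  sep <- rep(0, 256)
  sep[80:105 + 1] <- 10
  band <- find_nonoverlap_band(mk(sep, 0.1), g_lo)
  expect_equal(band, data.frame(start = 80L, end = 105L))
})

test_that("band intervals are disjoint, sorted, and within range", {
  set.seed(61)
  for (i in 1:10) {
    mk <- function() group_stats(lapply(1:4, function(j)
      make_curve(euler = cumsum(rnorm(256)))), "g")
    band <- find_nonoverlap_band(mk(), mk())
    if (nrow(band) == 0L) next
    expect_true(all(band$start <= band$end))
    expect_true(all(band$start >= 0) && all(band$end <= 255))
    if (nrow(band) > 1L) {
      expect_true(all(band$start[-1L] > band$end[-nrow(band)] + 1L))
    }
  }
})

test_that("band feature is the mean euler value over the band", {
  expect_equal(band_feature(make_curve(euler = rep(7.5, 256)), c(10, 20)), 7.5)
  expect_equal(band_feature(make_curve(euler = 0:255), c(80, 105)), 92.5)
  set.seed(67)
  e <- rnorm(256)
  expect_equal(band_feature(make_curve(euler = e), c(33, 200)),
               sum(e[34:201]) / 168)
  expect_error(band_feature(make_curve(), c(20, 10)), "band")
  expect_error(band_feature(make_curve(), c(-1, 10)), "band")
})
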