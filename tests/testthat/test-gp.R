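# small helper datasets ------------------------------------------------------

separable_data <- function(n_per_class = 20, margin = 1, seed = 1) {
  set.seed(seed)
  data.frame(
    label = rep(c("gradeII", "gradeIV"), each = n_per_class),
    euler_min = c(runif(n_per_class, -3, -margin / 2),
                  runif(n_per_class, margin / 2, 3)))
}

coinflip_data <- function(n_per_class = 50, seed = 1) {
  set.seed(seed)
  data.frame(label = sample(rep(c("gradeII", "gradeIV"), each = n_per_class)),
             euler_min = rnorm(2 * n_per_class),
             contour_max = rnorm(2 * n_per_class))
}

small_cfg <- function(...) {
  gp_config(max_generations = 15L, population_size = 30L,
            max_tree_length = 25L, ...)
}

# tree evaluation -------------------------------------------------------------

test_that("single-comparison trees follow the root convention", {
  lt_tree <- list(kind = "op", name = "LT",
                  args = list(list(kind = "feat", name = "euler_min"),
                              list(kind = "const", value = -700)))
  fv <- c(euler_min = -905)
  expect_equal(evaluate_tree(lt_tree, fv), "gradeIV")  # -905 < -700 is TRUE
  not_tree <- list(kind = "op", name = "NOT", args = list(lt_tree))
  expect_equal(evaluate_tree(not_tree, fv), "gradeII")
})

test_that("protected division returns 1 on a zero divisor", {
  tree <- list(kind = "op", name = "GT",
               args = list(list(kind = "op", name = "PDIV",
                                args = list(list(kind = "const", value = 5),
                                            list(kind = "const", value = 0))),
                           list(kind = "const", value = 0.5)))
  expect_equal(evaluate_tree(tree, c(euler_min = 0)), "gradeIV")  # 1 > 0.5
})

test_that("missing features are reported at evaluation", {
  tree <- list(kind = "op", name = "LT",
               args = list(list(kind = "feat", name = "contour_max"),
                           list(kind = "const", value = 1)))
  expect_error(evaluate_tree(tree, c(euler_min = 1)), "contour_max")
})

test_that("vectorized evaluation matches a scalar recursive interpreter", {
  set.seed(71)
  feats <- paste0("f", 1:6)
  ctx <- list(features = feats,
              ranges = data.frame(lo = rep(-5, 6), hi = rep(5, 6)))
  cfg <- gp_config(max_tree_depth = 6L, max_tree_length = 40L)
  X <- as.data.frame(matrix(rnorm(20 * 6), 20, 6,
                            dimnames = list(NULL, feats)))
  for (i in 1:100) {
    tree <- minkograde:::random_individual(cfg, ctx)
    vec <- evaluate_tree(tree, X)
    scalar <- vapply(seq_len(nrow(X)), function(r) {
      oracle_classify(tree, as.list(X[r, ]))
    }, character(1L))
    expect_identical(vec, scalar)
  }
})

# training --------------------------------------------------------------------

test_that("training is deterministic given the seed", {
  d <- separable_data(seed = 5)
  m1 <- gp_train(d, small_cfg(seed = 42L))
  m2 <- gp_train(d, small_cfg(seed = 42L))
  expect_identical(m1$tree, m2$tree)
  expect_identical(m1$train_accuracy, m2$train_accuracy)
})

test_that("a margin-separated one-feature problem is solved", {
  d <- separable_data(n_per_class = 20, margin = 1, seed = 9)
  solved <- vapply(1:10, function(s) {
    gp_train(d, gp_config(seed = s))$train_accuracy == 1
  }, logical(1L))
  expect_gte(sum(solved), 9L)
})

test_that("best-of-population beats the majority rate on coin-flip labels", {
  d <- coinflip_data(seed = 13)
  m <- gp_train(d, small_cfg(seed = 3L))
  expect_gt(m$train_accuracy, 0.5)
})

test_that("single-class training sets are rejected", {
  d <- separable_data(seed = 1)
  expect_error(gp_train(d[d$label == "gradeII", ], small_cfg()), "both classes")
})

test_that("returned models respect depth and length limits", {
  d <- separable_data(seed = 3)
  for (s in 1:5) {
    cfg <- gp_config(max_generations = 10L, population_size = 20L,
                     max_tree_depth = 4L, max_tree_length = 9L, seed = s)
    m <- gp_train(d, cfg)
    expect_lte(m$depth, 4L)
    expect_lte(m$length, 9L)
  }
})

test_that("random individuals always satisfy typing and limits", {
  set.seed(79)
  ctx <- list(features = c("a", "b"),
              ranges = data.frame(lo = c(0, -1), hi = c(1, 1)))
  cfg <- gp_config(max_tree_depth = 5L, max_tree_length = 12L)
  for (i in 1:200) {
    tree <- minkograde:::random_individual(cfg, ctx)
    expect_lte(minkograde:::tree_depth(tree), 5L)
    expect_lte(minkograde:::tree_length(tree), 12L)
    expect_equal(minkograde:::node_type(tree), "bool")
    out <- evaluate_tree(tree, data.frame(a = 0.3, b = -0.2))
    expect_true(out %in% c("gradeII", "gradeIV"))
  }
})

# cross-validation ------------------------------------------------------------

test_that("cross-validation recovers a separable problem", {
  d <- separable_data(n_per_class = 15, seed = 17)
  cv <- cross_validate(d, small_cfg(n_runs = 2L, n_folds = 5L, seed = 7L))
  expect_gte(cv$best_accuracy, 0.95)
  expect_length(cv$run_accuracies, 2L)
  expect_true(all(cv$run_accuracies >= 0 & cv$run_accuracies <= 1))
})

test_that("fold assignments are stratified partitions", {
  d <- separable_data(n_per_class = 12, seed = 19)
  cv <- cross_validate(d, small_cfg(n_runs = 1L, n_folds = 4L, seed = 1L))
  folds <- cv$runs[[1L]]$folds
  expect_equal(sort(unique(folds)), 1:4)
  for (k in 1:4) {
    expect_equal(sum(folds == k & d$label == "gradeII"), 3L)
    expect_equal(sum(folds == k & d$label == "gradeIV"), 3L)
  }
})

test_that("n_folds equal to the sample count gives leave-one-out", {
  d <- separable_data(n_per_class = 5, seed = 23)
  cv <- cross_validate(d, small_cfg(n_runs = 1L, n_folds = 10L, seed = 2L))
  folds <- cv$runs[[1L]]$folds
  expect_equal(sort(folds), 1:10)          # singleton folds partition the data
  expect_true(all(cv$runs[[1L]]$fold_accuracies %in% c(0, 1)))
})

test_that("a class smaller than n_folds is a contract error", {
  d <- separable_data(n_per_class = 4, seed = 29)
  expect_error(cross_validate(d, small_cfg(n_folds = 5L)), "n_folds")
})

test_that("held-out samples do not influence training", {
  d <- separable_data(n_per_class = 10, seed = 31)
  cfg <- small_cfg(n_runs = 1L, n_folds = 5L, seed = 11L)
  cv1 <- cross_validate(d, cfg)
  # perturb the features of one sample; models of the fold where it is held
  # out must be unchanged, since training there never saw it
  victim <- 1L
  d2 <- d
  d2$euler_min[victim] <- d2$euler_min[victim] + 100
  cv2 <- cross_validate(d2, cfg)
  k <- cv1$runs[[1L]]$folds[victim]
  expect_identical(cv1$runs[[1L]]$fold_models[[k]]$tree,
                   cv2$runs[[1L]]$fold_models[[k]]$tree)
})

test_that("grid search ranks all configurations non-increasingly", {
  d <- separable_data(n_per_class = 10, seed = 37)
  grid <- data.frame(max_generations = c(10L, 10L),
                     max_tree_length = c(25L, 50L))
  base <- small_cfg(n_runs = 1L, n_folds = 5L, seed = 3L)
  gs <- grid_search(d, grid, base)
  expect_equal(nrow(gs$table), 2L)
  expect_true(all(diff(gs$table$best_accuracy) <= 0))
  # a single-row grid reproduces a plain cross_validate call
  single <- grid_search(d, grid[2L, , drop = FALSE], base)
  direct <- cross_validate(d, gp_config(max_generations = 10L,
                                        population_size = 30L,
                                        max_tree_length = 50L,
                                        n_runs = 1L, n_folds = 5L, seed = 3L))
  expect_equal(single$results[[1L]]$run_accuracies, direct$run_accuracies)
  expect_identical(deparse_tree(single$results[[1L]]$best_model),
                   deparse_tree(direct$best_model))
})

test_that("the full reference grid has 24 configurations", {
  g <- gp_default_grid()
  expect_equal(nrow(g), 24L)
  expect_setequal(unique(g$max_generations), c(70L, 100L))
  expect_setequal(unique(g$mutation_probability_percent), c(10, 15))
  expect_setequal(unique(g$max_tree_depth), c(8L, 10L))
  expect_setequal(unique(g$max_tree_length), c(25L, 50L, 80L))
})

test_that("models survive a JSON round-trip", {
  d <- separable_data(seed = 41)
  m <- gp_train(d, small_cfg(seed = 19L))
  f <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, f)
  back <- read_model_json(f)
  expect_identical(deparse_tree(back), deparse_tree(m))
  X <- data.frame(euler_min = seq(-3, 3, length.out = 11))
  expect_identical(evaluate_tree(back, X), evaluate_tree(m, X))
})
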