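test_that("train/test splits are reproducible, disjoint, and stratified", {
  labs <- rep(c("a", "b"), c(30, 20))
  s1 <- split_train_test(50, 0.3, seed = 4, labels = labs)
  s2 <- split_train_test(50, 0.3, seed = 4, labels = labs)
  expect_identical(s1, s2)
  expect_length(intersect(s1$train, s1$test), 0)
  expect_setequal(c(s1$train, s1$test), 1:50)
  # class proportions preserved to within one sample
  expect_equal(sum(labs[s1$test] == "a"), 9)
  expect_equal(sum(labs[s1$test] == "b"), 6)
  expect_error(split_train_test(10, 0, seed = 1), "test_fraction")
})

test_that("stratified folds keep every class in every fold", {
  set.seed(1)
  labs <- rep(1:3, c(12, 9, 6))
  fold <- sparsevda:::make_folds(labs, 3)
  for (k in 1:3) expect_setequal(unique(labs[fold != k]), 1:3)
  expect_error(sparsevda:::make_folds(c(1, 1, 1, 2), 3), "2")
})

test_that("the model-size grid is log-spaced over half the feature space", {
  g <- k_grid_log(1000)
  expect_equal(g[1], 2)
  expect_equal(g[length(g)], 500)
  expect_true(all(diff(g) > 0))
  expect_true(all(g == round(g)))
})

test_that("epsilon tuning breaks ties toward the smaller radius", {
  set.seed(2)
  n <- 60
  y <- rep(1:2, each = n / 2)
  x <- matrix(rnorm(n * 4), n, 4)
  x[, 1] <- x[, 1] + ifelse(y == 1, 6, -6)   # trivially separable
  fold <- sparsevda:::make_folds(y, 3)
  cfg <- vda_cv_config(eps_grid = c(0.1, 0.3, 0.6), seed = 1)
  tg <- tune_eps_gamma(x, y, fold, cfg, class_order = 1:2)
  # all radii achieve perfect fold accuracy on a separable toy: smallest wins
  expect_true(all(tg$scores == 1))
  expect_equal(tg$eps, 0.1)
  expect_equal(tg$gamma, 0)
})

test_that("model-size tuning returns the smallest size attaining the max", {
  set.seed(3)
  n <- 60
  y <- rep(1:2, each = n / 2)
  x <- matrix(rnorm(n * 20), n, 20)
  x[, 5] <- x[, 5] + ifelse(y == 1, 4, -4)
  x[, 11] <- x[, 11] + ifelse(y == 1, -4, 4)
  fold <- sparsevda:::make_folds(y, 3)
  caches <- sparsevda:::build_fold_caches(x, y, fold, 1:2)
  tk <- tune_k(caches, eps = 0.3, variant = "row", grid = c(2, 4, 8, 16),
               class_order = 1:2)
  expect_lte(tk$k, 4)   # two informative features at high separation
  expect_equal(dim(tk$scores), c(4L, 3L))
})

test_that("nested cross-validation is deterministic and hygienic", {
  set.seed(4)
  n <- 90
  y <- rep(1:3, each = n / 3)
  x <- matrix(rnorm(n * 8), n, 8)
  x[, 2] <- x[, 2] + c(3, -3, 0)[y]
  x[, 6] <- x[, 6] + c(0, 3, -3)[y]
  cfg <- vda_cv_config(n_folds = 3, eps_grid = c(0.2, 0.5),
                       k_grid = c(2, 4, 8), seed = 7)
  cv1 <- nested_cv(x, y, cfg, variant = "row")
  cv2 <- nested_cv(x, y, cfg, variant = "row")
  expect_equal(cv1$chosen_k, cv2$chosen_k)
  expect_equal(cv1$test_error, cv2$test_error)
  expect_equal(cv1$final_fit$B, cv2$final_fit$B)
  # held-out samples never appear in any tuning fold
  expect_length(intersect(cv1$split$test, cv1$split$train), 0)
  expect_setequal(c(cv1$split$train, cv1$split$test), seq_len(n))
  expect_length(cv1$fold, length(cv1$split$train))
  expect_true(all(cv1$fold %in% 1:3))
  expect_lt(cv1$test_error, 20)
})

test_that("repeated CV aggregates supports and quantiles correctly", {
  set.seed(5)
  n <- 90
  y <- rep(1:2, each = n / 2)
  x <- matrix(rnorm(n * 10), n, 10)
  x[, 3] <- x[, 3] + ifelse(y == 1, 4, -4)
  cfg <- vda_cv_config(n_folds = 3, eps_grid = 0.3, k_grid = c(1, 2, 4),
                       n_repeats = 3, seed = 11)
  rep3 <- repeated_cv(x, y, cfg, variant = "row")
  expect_equal(nrow(rep3$replicates), 3L)
  expect_true(all(rep3$feature_counts <= 3))
  expect_true(all(rep3$feature_counts >= 0))
  # per-class table mirrors the top-feature layout: one row per top feature,
  # one column per class, counts bounded by the replicate count
  expect_equal(nrow(rep3$per_class_counts), length(rep3$top_features))
  expect_equal(ncol(rep3$per_class_counts), 2L)
  expect_true(all(rep3$per_class_counts <= 3))
  # quantiles match an independent order-statistics computation
  expect_equal(unname(rep3$size_quantiles),
               unname(quantile(rep3$replicates$support_size,
                               c(0.1, 0.5, 0.9), type = 7)))
  # single replicate: counts reduce to a 0/1 support indicator
  cfg1 <- vda_cv_config(n_folds = 3, eps_grid = 0.3, k_grid = c(1, 2),
                        n_repeats = 1, seed = 3)
  rep1 <- repeated_cv(x, y, cfg1, variant = "row")
  expect_true(all(rep1$feature_counts %in% c(0L, 1L)))
})
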