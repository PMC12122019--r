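#' Train/test split
#'
#' Splits `n` samples into disjoint, exhaustive training and test index sets.
#' With `stratified = TRUE` the split preserves class proportions to within
#' one sample per class.
#'
#' @param n sample count.
#' @param test_fraction fraction held out, in (0, 1).
#' @param seed optional integer seed.
#' @param stratified stratify by class?
#' @param labels class labels (required when stratified).
#' @return list with integer vectors `train` and `test`.
#' @export
split_train_test <- function(n, test_fraction, seed = NULL,
                             stratified = TRUE, labels = NULL) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  if (stratified) {
    if (is.null(labels) || length(labels) != n) {
      stop("stratified split needs 'labels' of length n")
    }
    test <- integer(0)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      m <- round(length(idx) * test_fraction)
      if (m > 0) test <- c(test, sample(idx, m))
    }
    test <- sort(test)
  } else {
    test <- sort(sample.int(n, round(n * test_fraction)))
  }
  list(train = setdiff(seq_len(n), test), test = test)
}

# fold assignment, stratified by class; errors when a class has fewer members
# than folds (it could otherwise vanish from a training fold entirely)
make_folds <- function(labels, K, stratified = TRUE) {
  n <- length(labels)
  fold <- integer(n)
  if (stratified) {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < K) {
        stop("class '", cl, "' has fewer than ", K, " members; cannot stratify")
      }
      fold[idx] <- sample(rep_len(seq_len(K), length(idx)))
    }
  } else {
    fold <- sample(rep_len(seq_len(K), n))
  }
  fold
}

#' Logarithmic model-size grid
#'
#' Candidate sparsity levels spread on a log scale between `k_min` and about
#' half the feature space, the coverage used for the model-size search.
#'
#' @param p number of features (or coefficients) available.
#' @param length grid length.
#' @param k_min smallest candidate.
#' @return increasing integer vector.
#' @export
k_grid_log <- function(p, length = 7L, k_min = 2L) {
  hi <- max(k_min, ceiling(p / 2))
  unique(pmin(p, pmax(1L, round(exp(seq(log(k_min), log(hi),
                                        length.out = length))))))
}

#' Cross-validation configuration
#'
#' @param n_folds folds `K` for the tuning phase; default 3 when the training
#'   set has fewer than 200 samples, 5 otherwise.
#' @param eps_grid candidate insensitivity radii (log-spaced in
#'   `[0.05, 0.70]`, below half the inter-vertex distance, by default).
#' @param gamma_grid candidate kernel scales; the linear model uses the
#'   singleton 0.
#' @param k_grid candidate model sizes for l0 constraints (default: a
#'   [k_grid_log()] over the feature space).
#' @param lambda_grid candidate l1 radii for l1 constraints.
#' @param test_fraction held-out fraction when no explicit test set is given.
#' @param n_repeats replicates for [repeated_cv()].
#' @param seed integer seed controlling every random choice.
#' @param stratified stratify splits and folds by class?
#' @return list of class `vda_cv_config`.
#' @export
vda_cv_config <- function(n_folds = NULL,
                          eps_grid = exp(seq(log(0.05), log(0.70),
                                             length.out = 7)),
                          gamma_grid = 0, k_grid = NULL, lambda_grid = NULL,
                          test_fraction = 0.2, n_repeats = 1L, seed = 1L,
                          stratified = TRUE) {
  stopifnot(length(eps_grid) >= 1, n_repeats >= 1)
  structure(list(n_folds = n_folds, eps_grid = sort(eps_grid),
                 gamma_grid = sort(gamma_grid), k_grid = k_grid,
                 lambda_grid = lambda_grid, test_fraction = test_fraction,
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed),
                 stratified = isTRUE(stratified)),
            class = "vda_cv_config")
}

# Per-fold training caches: standardized design, its thin SVD, one-hot labels,
# and the standardized validation block. Built once and reused across every
# (epsilon, k) pair, which is where the pipeline saves its time.
build_fold_caches <- function(x, y, fold, class_order, kernel = NULL,
                              gamma = NULL) {
  K <- max(fold)
  lapply(seq_len(K), function(k) {
    tr <- which(fold != k)
    va <- which(fold == k)
    std <- standardize_fit(x[tr, , drop = FALSE])
    xs <- standardize_apply(x[tr, , drop = FALSE], std)
    vs <- standardize_apply(x[va, , drop = FALSE], std)
    if (!is.null(kernel)) {
      A <- cbind(1, rbf_kernel(xs, xs, gamma))
      Aval <- cbind(1, rbf_kernel(vs, xs, gamma))
    } else {
      A <- cbind(1, xs)
      Aval <- cbind(1, vs)
    }
    list(A = A, Y = encode_labels(y[tr], class_order)$Y,
         Aval = Aval, yval = y[va],
         cache = build_svd_cache(A), train_idx = tr, val_idx = va)
  })
}

fold_accuracy <- function(fc, B, class_order) {
  pred <- classify_vertices(fc$Aval %*% B, class_order)
  mean(pred == fc$yval)
}

#' Tune the insensitivity radius and kernel scale
#'
#' K-fold cross-validation accuracy of the dense (unconstrained) VDA model
#' over the `(epsilon, gamma)` grid; returns the best pair, ties going to the
#' smaller `epsilon`, then the smaller `gamma`. The linear model fixes
#' `gamma = 0`.
#'
#' @param x,y training data.
#' @param fold fold assignment from `make_folds()`.
#' @param cfg a [vda_cv_config()].
#' @param class_order fixed class ordering.
#' @param kernel `NULL` or `"rbf"`.
#' @param controls,schedule solver settings.
#' @param fold_caches optional prebuilt caches for the linear model.
#' @return list with `eps`, `gamma`, the score matrix `scores`
#'   (grid x fold), and the caches for the winning `gamma`.
#' @export
tune_eps_gamma <- function(x, y, fold, cfg, class_order, kernel = NULL,
                           controls = vda_controls(),
                           schedule = vda_schedule(), fold_caches = NULL) {
  gammas <- if (is.null(kernel)) 0 else cfg$gamma_grid
  grid <- expand.grid(eps = cfg$eps_grid, gamma = gammas,
                      KEEP.OUT.ATTRS = FALSE)
  K <- max(fold)
  scores <- matrix(NA_real_, nrow(grid), K)
  caches_by_gamma <- list()
  for (g in unique(grid$gamma)) {
    key <- format(g, digits = 17)
    caches_by_gamma[[key]] <- if (is.null(kernel) && !is.null(fold_caches)) {
      fold_caches
    } else {
      build_fold_caches(x, y, fold, class_order, kernel, gamma = g)
    }
  }
  none <- vda_constraint("none")
  for (i in seq_len(nrow(grid))) {
    fcs <- caches_by_gamma[[format(grid$gamma[i], digits = 17)]]
    for (k in seq_len(K)) {
      fc <- fcs[[k]]
      res <- proximal_distance_fit(fc$A, fc$Y, grid$eps[i], none,
                                   schedule, controls, cache = fc$cache,
                                   has_intercept = TRUE)
      scores[i, k] <- fold_accuracy(fc, res$B_hat, class_order)
    }
  }
  mean_acc <- rowMeans(scores)
  # tie-break: smaller eps first, then smaller gamma
  ord <- order(grid$eps, grid$gamma)
  sel <- grid[ord[which.max(mean_acc[ord])], ]
  list(eps = sel$eps, gamma = sel$gamma, scores = scores,
       caches = caches_by_gamma[[format(sel$gamma, digits = 17)]])
}

#' Tune the model size
#'
#' K-fold accuracy per candidate size on the same folds used for
#' `(epsilon, gamma)`. Candidates are fitted from largest to smallest with
#' warm starts along the path; the smallest size attaining the maximum mean
#' accuracy (to machine tolerance) is selected.
#'
#' @param fold_caches caches from [tune_eps_gamma()] / `build_fold_caches()`.
#' @param eps tuned insensitivity radius.
#' @param variant constraint variant (`"row"`, `"col"`, `"global"`, or an l1
#'   variant, in which case `grid` is interpreted as lambda values).
#' @param grid candidate sizes (or l1 radii).
#' @param class_order fixed class ordering.
#' @param controls,schedule,method,polish solver settings.
#' @return list with the chosen `k`, the score matrix (size x fold), and the
#'   grid.
#' @export
tune_k <- function(fold_caches, eps, variant, grid, class_order,
                   controls = vda_controls(), schedule = vda_schedule(),
                   method = "direct", polish = FALSE) {
  is_l1 <- variant %in% c("l1", "l1row", "l1col")
  grid <- sort(grid, decreasing = TRUE)   # densest first: warm-start the path
  scores <- matrix(NA_real_, length(grid), length(fold_caches))
  for (f in seq_along(fold_caches)) {
    fc <- fold_caches[[f]]
    B_warm <- NULL
    for (i in seq_along(grid)) {
      con <- if (is_l1) vda_constraint(variant, lambda = grid[i])
             else vda_constraint(variant, k = grid[i])
      res <- proximal_distance_fit(fc$A, fc$Y, eps, con, schedule, controls,
                                   method = method, cache = fc$cache,
                                   has_intercept = TRUE, polish = polish,
                                   B_init = B_warm)
      B_warm <- res$B_hat
      scores[i, f] <- fold_accuracy(fc, res$B_hat, class_order)
    }
  }
  mean_acc <- rowMeans(scores)
  best <- max(mean_acc)
  chosen <- min(grid[mean_acc >= best - 1e-12])  # parsimony tie-break
  list(k = chosen, scores = scores[order(grid), , drop = FALSE],
       grid = sort(grid))
}

#' Nested cross-validation for sparse VDA
#'
#' The full pipeline: hold out a test set (unless one is supplied), tune
#' `(epsilon, gamma)` by K-fold cross-validation of the dense model, tune the
#' model size `k` on the same folds, refit on the whole training set at the
#' chosen hyperparameters, and score once on the held-out test samples, which
#' never participate in tuning.
#'
#' @param x,y data (training portion when `test` is supplied).
#' @param cfg a [vda_cv_config()].
#' @param variant constraint variant to tune (`"row"`, `"col"`, `"global"`,
#'   `"l1"`, `"l1row"`, `"l1col"`).
#' @param kernel `NULL` or `"rbf"`.
#' @param test optional list `list(x, y)` with an explicit test set (used by
#'   the simulation benchmarks, whose generator supplies independent test
#'   samples).
#' @param schedule,controls,method,polish solver settings.
#' @return object of class `vda_cv`: chosen hyperparameters, fold score
#'   matrices, the final fit, `test_error` in percent, and index bookkeeping.
#' @export
nested_cv <- function(x, y, cfg, variant = "row", kernel = NULL,
                      test = NULL, schedule = vda_schedule(),
                      controls = vda_controls(),
                      method = "direct", polish = FALSE) {
  x <- as.matrix(x)
  set.seed(cfg$seed)
  if (is.null(test)) {
    sp <- split_train_test(nrow(x), cfg$test_fraction,
                           stratified = cfg$stratified, labels = y)
    x_tr <- x[sp$train, , drop = FALSE]; y_tr <- y[sp$train]
    x_te <- x[sp$test, , drop = FALSE];  y_te <- y[sp$test]
    split <- sp
  } else {
    x_tr <- x; y_tr <- y
    x_te <- as.matrix(test$x); y_te <- test$y
    split <- NULL
  }
  class_order <- sort(unique(c(y_tr, y_te)))
  K <- cfg$n_folds
  if (is.null(K)) K <- if (length(y_tr) < 200) 3L else 5L
  fold <- make_folds(y_tr, K, cfg$stratified)

  fold_caches <- if (is.null(kernel)) {
    build_fold_caches(x_tr, y_tr, fold, class_order)
  } else NULL
  tg <- tune_eps_gamma(x_tr, y_tr, fold, cfg, class_order, kernel,
                       controls, schedule, fold_caches)

  is_l1 <- variant %in% c("l1", "l1row", "l1col")
  grid <- if (is_l1) cfg$lambda_grid else cfg$k_grid
  if (is.null(grid)) {
    if (is_l1) stop("l1 variants need cfg$lambda_grid")
    grid <- k_grid_log(if (is.null(kernel)) ncol(x_tr) else nrow(x_tr))
  }
  # fold fits are scored without the polish refit: polishing inflates the
  # apparent accuracy of overly large models and distorts the size search
  tk <- tune_k(tg$caches, tg$eps, variant, grid, class_order,
               controls, schedule, method, polish = FALSE)

  # final refit: follow the model-size path down to the chosen value with warm
  # starts, mirroring how the fold fits were produced
  path <- sort(unique(c(grid[grid >= tk$k], tk$k)), decreasing = TRUE)
  gam <- if (!is.null(kernel)) tg$gamma else NULL
  cache_full <- if (method == "direct") {
    std <- standardize_fit(x_tr)
    xs <- standardize_apply(x_tr, std)
    base <- if (!is.null(kernel)) rbf_kernel(xs, xs, gam) else xs
    build_svd_cache(cbind(1, base))
  } else NULL
  B_warm <- NULL
  for (kk in path) {
    con <- if (is_l1) vda_constraint(variant, lambda = kk)
           else vda_constraint(variant, k = kk)
    fit <- vda_fit(x_tr, y_tr, con, epsilon = tg$eps, kernel = kernel,
                   gamma = gam, schedule = schedule, controls = controls,
                   method = method, polish = polish && kk == tk$k,
                   class_order = class_order, B_init = B_warm,
                   svd_cache = cache_full)
    B_warm <- fit$B
  }
  pred <- predict(fit, x_te)
  structure(list(chosen_eps = tg$eps, chosen_gamma = tg$gamma,
                 chosen_k = tk$k,
                 eps_gamma_scores = tg$scores, k_scores = tk$scores,
                 k_grid = tk$grid, variant = variant,
                 test_error = 100 * mean(pred != y_te),
                 final_fit = fit, n_folds = K, fold = fold, split = split,
                 seed = cfg$seed),
            class = "vda_cv")
}

#' @export
print.vda_cv <- function(x, ...) {
  cat(sprintf(
    "Nested CV sparse VDA (%s): eps = %.3g, gamma = %.3g, k = %g\n",
    x$variant, x$chosen_eps, x$chosen_gamma, x$chosen_k))
  cat(sprintf("test error = %.2f%% (%d folds, seed %d)\n",
              x$test_error, x$n_folds, x$seed))
  invisible(x)
}

#' Repeated cross-validation stability report
#'
#' Re-runs [nested_cv()] with distinct seeds and aggregates the selected
#' supports: per-feature (and per-class) selection counts, the empirical
#' 10/50/90% quantiles of the selected model size and test error, and signed
#' coefficient summaries for the most frequently selected features.
#'
#' @inheritParams nested_cv
#' @param top_n features retained in the per-class frequency table.
#' @return object of class `vda_stability` with `replicates` (one row per
#'   replicate: seed, eps, gamma, k, test error, support size),
#'   `feature_counts`, `per_class_counts` (top_n x c), `size_quantiles`,
#'   `error_quantiles`, and `coef_summary`.
#' @export
repeated_cv <- function(x, y, cfg, variant = "row", kernel = NULL,
                        test = NULL, schedule = vda_schedule(),
                        controls = vda_controls(), method = "direct",
                        polish = FALSE, top_n = 50L) {
  x <- as.matrix(x)
  p <- ncol(x)
  runs <- vector("list", cfg$n_repeats)
  for (r in seq_len(cfg$n_repeats)) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r - 1L
    runs[[r]] <- nested_cv(x, y, cfg_r, variant, kernel, test,
                           schedule, controls, method, polish)
  }
  cc <- runs[[1]]$final_fit$c
  feat_counts <- integer(p)
  per_class <- matrix(0L, p, cc)
  coef_sum <- matrix(0, p, cc)
  reps <- data.frame(seed = integer(0), eps = numeric(0), gamma = numeric(0),
                     k = numeric(0), test_error = numeric(0),
                     support_size = integer(0))
  for (r in seq_along(runs)) {
    cvr <- runs[[r]]
    sup <- cvr$final_fit$support
    feat_counts[sup$overall] <- feat_counts[sup$overall] + 1L
    for (j in seq_len(cc)) {
      per_class[sup$per_class[[j]], j] <- per_class[sup$per_class[[j]], j] + 1L
    }
    Bsl <- cvr$final_fit$B[-1L, , drop = FALSE]
    coef_sum <- coef_sum + Bsl
    reps <- rbind(reps, data.frame(
      seed = cvr$seed, eps = cvr$chosen_eps, gamma = cvr$chosen_gamma,
      k = cvr$chosen_k, test_error = cvr$test_error,
      support_size = length(sup$overall)))
  }
  qs <- c(0.1, 0.5, 0.9)
  top <- order(feat_counts, decreasing = TRUE)[seq_len(min(top_n, p))]
  top <- top[feat_counts[top] > 0]
  structure(list(
    replicates = reps,
    feature_counts = feat_counts,
    per_class_counts = per_class[top, , drop = FALSE],
    top_features = top,
    size_quantiles = stats::quantile(reps$support_size, qs, type = 7),
    error_quantiles = stats::quantile(reps$test_error, qs, type = 7),
    coef_summary = coef_sum[top, , drop = FALSE] / cfg$n_repeats,
    n_repeats = cfg$n_repeats),
    class = "vda_stability")
}

#' @export
print.vda_stability <- function(x, ...) {
  cat(sprintf("Repeated CV stability report (%d replicates)\n", x$n_repeats))
  cat("model size quantiles (10/50/90%):",
      paste(x$size_quantiles, collapse = " / "), "\n")
  cat("test error quantiles (10/50/90%):",
      paste(round(x$error_quantiles, 2), collapse = " / "), "%\n")
  invisible(x)
}
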