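test_that("the Toeplitz design has the requested covariance", {
  X0 <- toeplitz_gaussian_design(4000, 6, 0, seed = 1)
  C0 <- cor(X0)
  expect_true(all(abs(C0[upper.tri(C0)]) < 3 / sqrt(4000)))
  X9 <- toeplitz_gaussian_design(10000, 8, 0.9, seed = 2)
  C9 <- cor(X9)
  adj <- C9[cbind(1:7, 2:8)]
  expect_true(all(abs(adj - 0.9) < 0.02))
  expect_true(abs(C9[1, 3] - 0.81) < 0.03)
  expect_identical(toeplitz_gaussian_design(50, 5, 0.5, seed = 3),
                   toeplitz_gaussian_design(50, 5, 0.5, seed = 3))
  expect_error(toeplitz_gaussian_design(10, 5, 1), "corr")
})

test_that("true slope matrices have the advertised support structure", {
  hom <- sample_true_slopes(200, 3, 30, "homogeneous", seed = 1)
  expect_equal(sum(rowSums(hom$B_star != 0) > 0), 30)
  expect_setequal(which(rowSums(hom$B_star != 0) > 0), hom$support)
  expect_true(all(hom$B_star %in% c(-1, 0, 1)))
  het <- sample_true_slopes(200, 3, 30, "heterogeneous", seed = 2)
  sizes <- unname(lengths(het$per_class_support))
  expect_equal(sizes, rep(10L, 3))
  expect_length(Reduce(intersect, het$per_class_support), 0)
  # informative submatrix keeps full column rank across seeds
  for (s in 1:25) {
    tr <- sample_true_slopes(60, 3, 12, sample(c("homogeneous",
                                                 "heterogeneous"), 1),
                             seed = s)
    expect_equal(qr(tr$B_star[tr$support, ])$rank, 3L)
  }
  expect_error(sample_true_slopes(10, 3, 20), "exceed")
  expect_error(sample_true_slopes(100, 3, 10, "heterogeneous"), "divide")
})

test_that("labels come from the shared nearest-vertex rule", {
  set.seed(3)
  B <- sample_true_slopes(40, 3, 9, seed = 4)$B_star
  X <- matrix(rnorm(25 * 40), 25, 40)
  expect_identical(assign_labels(X, B),
                   classify_vertices(X %*% B, 1:3))
  x1 <- matrix(0, 1, 40)
  x1[1, ] <- qr.solve(t(B) %*% diag(40), c(1, 0, 0))  # B^T x = e_1
  expect_equal(assign_labels(x1, B), 1L)
  expect_error(assign_labels(X, matrix(0, 40, 3)), "degenerate")
})

test_that("noise variance tracks the signal-to-noise ratio", {
  Y <- encode_labels(rep(1:2, each = 5000))$Y
  s2 <- noise_sigma_from_snr(Y, 1)
  expect_equal(s2, 0.25, tolerance = 1e-3)   # balanced Bernoulli variance
  expect_equal(noise_sigma_from_snr(Y, 10), s2 / 10, tolerance = 1e-12)
  expect_lt(noise_sigma_from_snr(Y, 1e9), 1e-9)
  expect_warning(noise_sigma_from_snr(matrix(1, 10, 1), 1), "constant")
})

test_that("the shift construction satisfies its defining identity", {
  for (s in 1:10) {
    set.seed(s)
    p <- 50; n <- 40; cc <- 3
    tr <- sample_true_slopes(p, cc, 9, seed = s)
    X <- matrix(rnorm(n * p), n, p)
    y <- assign_labels(X, tr$B_star)
    Y <- encode_labels(y, 1:cc)$Y
    E <- matrix(rnorm(n * cc, sd = 0.2), n, cc)
    sh <- apply_shift(X, tr$B_star, Y, E, tr$support)
    expect_lt(max(abs(sh$X_shifted %*% tr$B_star + E - Y)), 1e-9)
    expect_true(all(sh$shift[, -tr$support] == 0))
    # a design already consistent with noiseless labels needs no shift
    sh0 <- apply_shift(X, tr$B_star, X %*% tr$B_star, 0 * E, tr$support)
    expect_lt(max(abs(sh0$shift)), 1e-9)
  }
})

test_that("the full generator is reproducible and internally consistent", {
  for (regime in c("homogeneous", "heterogeneous")) {
    sim <- simulate_classification(80, 60, 3, 9, 0.5, 5, regime = regime,
                                   n_test = 70, seed = 21)
    Y <- encode_labels(sim$y_train, 1:3)$Y
    expect_lt(max(abs(sim$x_train %*% sim$truth$B_star + sim$truth$noise - Y)),
              1e-9)
    expect_equal(dim(sim$x_test), c(70L, 60L))
    expect_equal(stats::sd(sim$truth$noise), sqrt(sim$truth$sigma2),
                 tolerance = 0.15)
    sim2 <- simulate_classification(80, 60, 3, 9, 0.5, 5, regime = regime,
                                    n_test = 70, seed = 21)
    expect_identical(sim$x_train, sim2$x_train)
    expect_identical(sim$y_test, sim2$y_test)
  }
  # the oracle classifier approaches zero error as the SNR grows
  sim <- simulate_classification(50, 40, 3, 9, 0.1, 1e6, n_test = 800,
                                 seed = 22)
  pred <- classify_vertices(sim$x_test %*% sim$truth$B_star, 1:3)
  expect_lt(mean(pred != sim$y_test), 0.01)
})

test_that("support metrics count true and predicted positives", {
  expect_equal(unname(support_metrics(1:30, 1:30)), c(1, 1))
  expect_equal(unname(support_metrics(1:60, 1:30)), c(1, 0.5))
  expect_equal(unname(support_metrics(integer(0), 1:5)), c(0, 0))
  expect_equal(unname(support_metrics(integer(0), integer(0))), c(1, 1))
  # heterogeneous: per class, then averaged
  est <- list(c(1, 2), c(3, 4), c(5, 6))
  tru <- list(c(1, 2), c(3, 9), c(7, 8))
  expect_equal(unname(support_metrics(est, tru)),
               c(mean(c(1, 0.5, 0)), mean(c(1, 0.5, 0))))
})

test_that("the circles toy has irreducible error equal to the flip rate", {
  # analytically: labels are flipped with probability 0.2 after a separable
  # assignment, so even the generating rule errs exactly 20% in expectation
  d <- toy_nonlinear("circles", n = 20000, flip = 0.2, seed = 31)
  r <- sqrt(rowSums(d$x^2))
  bayes_pred <- ifelse(r < 1.5, 1L, 2L)
  expect_lt(abs(mean(bayes_pred != d$y) - 0.2), 0.01)
  # with no flips a radius threshold is perfect
  d0 <- toy_nonlinear("circles", n = 2000, flip = 0, seed = 32)
  r0 <- sqrt(rowSums(d0$x^2))
  expect_equal(mean(ifelse(r0 < 1.5, 1L, 2L) != d0$y), 0)
  expect_error(toy_nonlinear("hexagons"), "arg")
})

test_that("high-SNR overdetermined fits recover the support", {
  sim <- simulate_classification(2000, 1000, 3, 30, 0.1, 10, seed = 33)
  fit <- vda_fit(sim$x_train, sim$y_train, vda_constraint("row", k = 30),
                 epsilon = 0.5)
  m <- support_metrics(fit$support$overall, sim$truth$support)
  expect_gt(m["tpr"], 0.9)
  expect_gt(m["ppv"], 0.9)
})
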