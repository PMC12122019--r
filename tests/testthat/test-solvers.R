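test_that("the SVD cache reconstructs the design at numerical rank", {
  expect_equal(build_svd_cache(diag(4))$d, rep(1, 4))
  set.seed(1)
  A <- matrix(rnorm(20 * 5), 20, 5)
  cc <- build_svd_cache(A)
  expect_lt(max(abs(cc$U %*% (cc$d * t(cc$V)) - A)), 1e-10)
  expect_lt(max(abs(crossprod(cc$U) - diag(cc$r))), 1e-10)
  expect_lt(max(abs(crossprod(cc$V) - diag(cc$r))), 1e-10)
  r1 <- build_svd_cache(outer(rnorm(8), rnorm(3)))
  expect_equal(r1$r, 1L)
  expect_error(build_svd_cache(matrix(c(1, NA), 1, 2)), "finite")
})

test_that("the direct MM update solves the ridge system exactly", {
  set.seed(2)
  n <- 30; q <- 8; cc <- 3
  A <- matrix(rnorm(n * q), n, q)
  Z <- matrix(rnorm(n * cc), n, cc)
  P <- matrix(rnorm(q * cc), q, cc)
  st <- structure(list(Z = Z, P = P), class = "vda_surrogate")
  cache <- build_svd_cache(A)
  for (rho in c(0.05, 1, 50)) {
    B <- mm_direct_update(st, cache, rho)
    Bref <- solve(crossprod(A) / n + rho * diag(q),
                  crossprod(A, Z) / n + rho * P)
    expect_equal(B, Bref, tolerance = 1e-8)
  }
  # identity design: elementwise closed form
  Ai <- diag(5)
  sti <- structure(list(Z = matrix(rnorm(10), 5, 2),
                        P = matrix(rnorm(10), 5, 2)), class = "vda_surrogate")
  Bi <- mm_direct_update(sti, build_svd_cache(Ai), 2)
  expect_equal(Bi, (sti$Z / 5 + 2 * sti$P) / (1 / 5 + 2), tolerance = 1e-10)
  # overwhelming penalty pins the update to the projection
  Bp <- mm_direct_update(st, cache, 1e8)
  expect_lt(max(abs(Bp - P)), 1e-6)
  expect_error(mm_direct_update(st, cache, 0), "positive")
})

test_that("Woodbury path agrees with a dense solve when p exceeds n", {
  set.seed(3)
  n <- 10; q <- 25
  A <- matrix(rnorm(n * q), n, q)
  st <- structure(list(Z = matrix(rnorm(n * 2), n, 2),
                       P = matrix(rnorm(q * 2), q, 2)),
                  class = "vda_surrogate")
  B <- mm_direct_update(st, build_svd_cache(A), 0.3)
  Bref <- solve(crossprod(A) / n + 0.3 * diag(q),
                crossprod(A, st$Z) / n + 0.3 * st$P)
  expect_equal(B, Bref, tolerance = 1e-8)
})

test_that("the steepest descent step is the exact line minimizer", {
  set.seed(4)
  pr <- random_problem(20, 5, 3)
  con <- vda_constraint("row", k = 2)
  anchor <- matrix(rnorm(pr$q * 3, sd = 0.4), pr$q, 3)
  st <- surrogate_responses(anchor, pr$A, pr$Y, 0.4)
  st$P <- project_constraint(anchor, con, has_intercept = TRUE)
  rho <- 0.8
  up <- steepest_descent_update(st, pr$A, rho)
  G <- surrogate_gradient(anchor, st, pr$A, rho)
  vals <- vapply(seq(0, 2.5 * up$step, length.out = 51), function(g) {
    surrogate_value(anchor - g * G, st, pr$A, rho)
  }, 0)
  expect_lte(surrogate_value(up$B, st, pr$A, rho), min(vals) + 1e-12)
  # zero design: step reduces to 1/rho
  A0 <- matrix(0, 6, 4)
  st0 <- structure(list(B_anchor = matrix(1, 4, 2), Z = matrix(1, 6, 2),
                        outside = rep(TRUE, 6), P = matrix(0, 4, 2)),
                   class = "vda_surrogate")
  expect_equal(steepest_descent_update(st0, A0, 2)$step, 1 / 2)
  # stationary anchor: no move
  stz <- st0; stz$P <- stz$B_anchor
  expect_equal(steepest_descent_update(stz, A0, 2)$step, 0)
})

test_that("inner solves descend monotonically and stop at stationarity", {
  set.seed(5)
  for (rep in 1:10) {
    pr <- random_problem(25, 6, 3, seed = 100 + rep)
    con <- vda_constraint("row", k = 3)
    ctl <- vda_controls(grad_tol = 1e-6)
    for (method in c("direct", "steepest")) {
      res <- inner_solve(matrix(0, pr$q, 3), pr$A, pr$Y, 0.3, con, 0.5, ctl,
                         method = method, has_intercept = TRUE)
      expect_true(all(diff(res$objective_trace) <= 1e-10))
    }
  }
  # an already-stationary start returns immediately
  pr <- random_problem(25, 6, 3)
  con <- vda_constraint("row", k = 6)   # vacuous at p = 6
  ctl <- vda_controls(grad_tol = 1e-8, max_inner = 2000)
  res <- inner_solve(matrix(0, pr$q, 3), pr$A, pr$Y, 0.3, con, 1, ctl,
                     has_intercept = TRUE)
  res2 <- inner_solve(res$B, pr$A, pr$Y, 0.3, con, 1, ctl,
                      has_intercept = TRUE)
  expect_equal(res2$iters, 0L)
  expect_true(res2$converged)
})

test_that("direct and steepest updates reach the same stationary point", {
  pr <- random_problem(30, 5, 3, seed = 6)
  con <- vda_constraint("row", k = 2)
  ctl <- vda_controls(grad_tol = 1e-9, max_inner = 5000)
  rd <- inner_solve(matrix(0, pr$q, 3), pr$A, pr$Y, 0.4, con, 2, ctl,
                    method = "direct", has_intercept = TRUE)
  rs <- inner_solve(matrix(0, pr$q, 3), pr$A, pr$Y, 0.4, con, 2, ctl,
                    method = "steepest", has_intercept = TRUE)
  expect_true(rd$converged && rs$converged)
  expect_lt(sqrt(sum((rd$B - rs$B)^2)), 1e-5)
})

test_that("the unconstrained solve matches a generic smooth optimizer", {
  pr <- random_problem(40, 4, 2, seed = 7)
  ctl <- vda_controls(grad_tol = 1e-9, max_inner = 2000)
  fit <- proximal_distance_fit(pr$A, pr$Y, 0.35, vda_constraint("none"),
                               vda_schedule(), ctl, has_intercept = TRUE)
  ref <- optim(rep(0, pr$q * 2), function(b) {
    epsilon_risk(matrix(b, pr$q, 2), pr$A, pr$Y, 0.35)
  }, method = "BFGS", control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(epsilon_risk(fit$B_hat, pr$A, pr$Y, 0.35), ref$value,
               tolerance = 1e-4)
})

test_that("proximal distance fits are exactly feasible and recover a toy", {
  # two well-separated Gaussian blobs driven by 2 of 10 features
  set.seed(8)
  n <- 80
  y <- rep(1:2, each = n / 2)
  x <- matrix(rnorm(n * 10), n, 10)
  x[, 3] <- x[, 3] + ifelse(y == 1, 4, -4)
  x[, 7] <- x[, 7] + ifelse(y == 1, -4, 4)
  fit <- vda_fit(x, y, vda_constraint("row", k = 2))
  expect_setequal(fit$support$overall, c(3L, 7L))
  expect_equal(unname(100 * mean(predict(fit, x) != y)), 0)
  # vacuous constraint: exits on the first annealing step with zero distance
  fv <- vda_fit(x, y, vda_constraint("row", k = 10))
  expect_equal(length(fv$dist_trace), 1L)
  expect_equal(fv$dist_trace, 0)
  # feasibility audit across random problems
  for (rep in 1:20) {
    pr <- random_problem(30, 8, 3, seed = 200 + rep)
    con <- vda_constraint(sample(c("row", "col", "global"), 1),
                          k = sample(2:5, 1))
    fit <- proximal_distance_fit(pr$A, pr$Y, 0.4, con, vda_schedule(),
                                 vda_controls(), has_intercept = TRUE)
    expect_identical(distance_to_set(fit$B_hat, con, has_intercept = TRUE), 0)
    expect_true(all(is.finite(fit$dist_trace)))
  }
})

test_that("warm starts do not increase total inner iterations (report only)", {
  pr <- random_problem(40, 10, 3, seed = 9)
  con <- vda_constraint("row", k = 3)
  cold <- proximal_distance_fit(pr$A, pr$Y, 0.4, con, vda_schedule(),
                                vda_controls(), has_intercept = TRUE)
  warm <- proximal_distance_fit(pr$A, pr$Y, 0.4, con, vda_schedule(),
                                vda_controls(), has_intercept = TRUE,
                                B_init = cold$B_hat)
  # a warm start from the solution should not need more work than cold
  expect_lte(warm$inner_iters, cold$inner_iters)
})
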