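#' Solver controls
#'
#' Tolerances and iteration limits for the proximal distance solver.
#'
#' @param grad_tol gradient stopping tolerance `delta_g` for the inner loop,
#'   `||grad f_rho(B)||_F <= delta_g`. Default `NULL` means the scale-aware
#'   value `1e-4 * sqrt(q * c)` is filled in once the problem dimensions are
#'   known.
#' @param dist_tol outer tolerance `delta_d` on the distance `q_t` from the
#'   iterate to the constraint set.
#' @param dist_change_tol outer tolerance `delta_q` on `|q_t - q_{t-1}|`; a
#'   stalled distance also counts as closeness, which avoids needless work at
#'   very large `rho`.
#' @param max_inner cap on inner (MM) iterations per annealing step.
#' @param accel use Nesterov extrapolation with weights `(m - 1)/(m + 2)` and
#'   restart on objective increase.
#' @return list of class `vda_controls`.
#' @export
vda_controls <- function(grad_tol = NULL, dist_tol = 1e-3,
                         dist_change_tol = 1e-6, max_inner = 500L,
                         accel = TRUE) {
  stopifnot(is.null(grad_tol) || grad_tol > 0, dist_tol > 0,
            dist_change_tol > 0, max_inner >= 1)
  structure(list(grad_tol = grad_tol, dist_tol = dist_tol,
                 dist_change_tol = dist_change_tol,
                 max_inner = as.integer(max_inner), accel = isTRUE(accel)),
            class = "vda_controls")
}

#' Annealing schedule for the distance penalty
#'
#' The outer loop solves a sequence of subproblems with penalty coefficients
#' `rho_t = min(rho_max, rho0 * mult^t)`, warm-starting each from the last.
#' Convergence is declared as soon as the gradient condition and the distance
#' condition both hold, even before `rho` reaches `rho_max` (early exit).
#'
#' @param rho0 initial penalty coefficient. The default 0.01 keeps the first
#'   annealing steps loss-driven: on the `1/(2n)`-normalized risk a unit
#'   starting penalty is already strong enough to lock in whatever support the
#'   first ridge solve happens to favor.
#' @param mult geometric growth factor, > 1.
#' @param rho_max cap on the penalty coefficient.
#' @param max_outer cap on annealing steps; default allows the schedule to
#'   reach `rho_max` plus a few extra steps there.
#' @return list of class `vda_schedule`.
#' @export
vda_schedule <- function(rho0 = 0.01, mult = 1.5, rho_max = 1e6,
                         max_outer = NULL) {
  stopifnot(rho0 > 0, mult > 1, rho_max >= rho0)
  if (is.null(max_outer)) {
    max_outer <- ceiling(log(rho_max / rho0) / log(mult)) + 5L
  }
  structure(list(rho0 = rho0, mult = mult, rho_max = rho_max,
                 max_outer = as.integer(max_outer)),
            class = "vda_schedule")
}

#' Thin SVD cache for the design matrix
#'
#' Extracts the thin singular value decomposition `A = U diag(d) V^T`
#' truncated at the numerical rank. The cache is computed once per design and
#' reused across every `(k, rho)` setting: via the Woodbury identity the ridge
#' system of the direct MM update reduces to re-inverting a diagonal matrix
#' that depends only on the singular values, `n`, and `rho`.
#'
#' @param design numeric design matrix (`n x q`), all entries finite.
#' @return list of class `vda_svd` with `U`, `d`, `V`, rank `r`, and `n`.
#' @export
build_svd_cache <- function(design) {
  design <- as.matrix(design)
  if (length(design) == 0L) stop("'design' is empty")
  if (!all(is.finite(design))) stop("'design' has non-finite entries")
  s <- svd(design)
  tol <- max(dim(design)) * .Machine$double.eps * max(s$d, 0)
  r <- max(1L, sum(s$d > tol))
  structure(list(U = s$u[, seq_len(r), drop = FALSE],
                 d = s$d[seq_len(r)],
                 V = s$v[, seq_len(r), drop = FALSE],
                 r = r, n = nrow(design)),
            class = "vda_svd")
}

#' Direct MM update via thin SVD and Woodbury
#'
#' Minimizes the penalized surrogate exactly:
#' `B = (n^{-1} A^T A + rho I)^{-1} (n^{-1} A^T Z + rho P)`. Using the cached
#' thin SVD, the inverse acts as `1/rho` on the null space of `A` and as
#' `1/(d_i^2/n + rho)` along the right singular vectors, so only a diagonal
#' depending on `(d, n, rho)` changes when `rho` changes.
#'
#' @param state a [surrogate_responses()] result with `P` filled in.
#' @param cache a [build_svd_cache()] of the design matrix.
#' @param rho penalty coefficient, strictly positive (the unregularized solve
#'   is a separate code path).
#' @return the updated coefficient matrix.
#' @export
mm_direct_update <- function(state, cache, rho) {
  if (rho <= 0) stop("'rho' must be positive; use the rho = 0 code path")
  if (is.null(state$P)) stop("surrogate state has no projection 'P'")
  n <- cache$n
  M <- cache$V %*% (cache$d * crossprod(cache$U, state$Z)) / n + rho * state$P
  dd <- cache$d^2 / n
  coef <- -dd / (rho * (dd + rho))          # 1/(dd + rho) - 1/rho, stably
  M / rho + cache$V %*% (coef * crossprod(cache$V, M))
}

#' Exact-step steepest descent update
#'
#' One gradient step on the quadratic surrogate with the closed-form exact
#' line minimizer
#' `gamma = ||G||_F^2 / (n^{-1} ||A G||_F^2 + rho ||G||_F^2)`,
#' where `G` is the surrogate gradient at the anchor. A zero gradient signals
#' stationarity and returns the anchor unchanged with step 0. This path avoids
#' the SVD entirely and suits problems too large to factor.
#'
#' @inheritParams mm_direct_update
#' @param A design matrix.
#' @return list with the updated matrix `B` and the step size `step`.
#' @export
steepest_descent_update <- function(state, A, rho) {
  n <- nrow(A)
  G <- surrogate_gradient(state$B_anchor, state, A, rho)
  g2 <- sum(G^2)
  if (g2 == 0) return(list(B = state$B_anchor, step = 0))
  AG <- A %*% G
  gamma <- g2 / (sum(AG^2) / n + rho * g2)
  list(B = state$B_anchor - gamma * G, step = gamma)
}

# shifted responses + bookkeeping from a precomputed prediction matrix
.shifted_responses <- function(AB, Y, epsilon) {
  R <- Y - AB
  rn <- sqrt(rowSums(R^2))
  out <- rn > epsilon
  Z <- AB
  if (any(out)) {
    w <- (rn[out] - epsilon) / rn[out]
    Z[out, ] <- w * Y[out, , drop = FALSE] + (1 - w) * AB[out, , drop = FALSE]
  }
  list(Z = Z, outside = out)
}

# gradient of f_rho at B via MM tangency, given Z/outside computed at B
.grad_at <- function(B, A, AB, Z, outside, P, rho, n) {
  G <- if (any(outside)) {
    -crossprod(A[outside, , drop = FALSE],
               (Z - AB)[outside, , drop = FALSE]) / n
  } else {
    matrix(0, nrow(B), ncol(B))
  }
  if (rho > 0) G <- G + rho * (B - P)
  G
}

#' Inner solve at fixed penalty strength
#'
#' Iterates surrogate construction and minimization (direct or steepest
#' descent) at fixed `rho` until the gradient condition
#' `||grad f_rho(B_m)||_F <= delta_g` holds or `max_inner` is reached. The
#' gradient is evaluated through the MM tangency identity. With acceleration
#' on, iterates are extrapolated with Nesterov weights `(m-1)/(m+2)` and the
#' momentum restarts whenever the penalized objective would increase, so the
#' objective trace is nonincreasing.
#'
#' @param B_init starting coefficient matrix (`q x c`).
#' @param A design matrix (`n x q`).
#' @param Y one-hot labels (`n x c`).
#' @param epsilon insensitivity radius.
#' @param constraint a [vda_constraint()].
#' @param rho penalty coefficient, positive.
#' @param controls a [vda_controls()] (with `grad_tol` resolved).
#' @param method `"direct"` (thin SVD + Woodbury) or `"steepest"`.
#' @param cache [build_svd_cache()] of `A`; required for `method = "direct"`.
#' @param has_intercept is row 1 of `B` an intercept row?
#' @return list with `B`, `AB`, projection `P`, distance `dist`, objective
#'   `f`, `grad_norm`, iteration count `iters`, `converged` flag, and the
#'   per-iteration `objective_trace`.
#' @export
inner_solve <- function(B_init, A, Y, epsilon, constraint, rho, controls,
                        method = c("direct", "steepest"), cache = NULL,
                        has_intercept = FALSE) {
  method <- match.arg(method)
  if (method == "direct" && is.null(cache)) cache <- build_svd_cache(A)
  stopifnot(rho > 0)
  n <- nrow(A)
  gtol <- controls$grad_tol
  if (is.null(gtol)) gtol <- 1e-4 * sqrt(length(B_init))

  B <- B_init
  AB <- A %*% B
  P <- project_constraint(B, constraint, has_intercept)
  sr <- .shifted_responses(AB, Y, epsilon)
  f_cur <- risk_from_pred(AB, Y, epsilon) + rho / 2 * sum((B - P)^2)
  G <- .grad_at(B, A, AB, sr$Z, sr$outside, P, rho, n)
  gn <- sqrt(sum(G^2))
  if (gn <= gtol) {
    return(list(B = B, AB = AB, P = P,
                dist = sqrt(sum((B - P)^2)), f = f_cur, grad_norm = gn,
                iters = 0L, converged = TRUE, objective_trace = numeric(0)))
  }

  B_prev <- B
  AB_prev <- AB
  m_eff <- 0L                # momentum counter, reset on restart
  converged <- FALSE
  trace <- numeric(controls$max_inner)
  take_step <- function(Banc, ABanc) {
    Panc <- project_constraint(Banc, constraint, has_intercept)
    src <- .shifted_responses(ABanc, Y, epsilon)
    st <- list(B_anchor = Banc, Z = src$Z, outside = src$outside, P = Panc)
    class(st) <- "vda_surrogate"
    if (method == "direct") mm_direct_update(st, cache, rho)
    else steepest_descent_update(st, A, rho)$B
  }

  for (m in seq_len(controls$max_inner)) {
    mom <- if (controls$accel && m_eff > 0L) (m_eff - 1) / (m_eff + 2) else 0
    if (mom > 0) {
      B_new <- take_step(B + mom * (B - B_prev), AB + mom * (AB - AB_prev))
    } else {
      B_new <- take_step(B, AB)
    }
    AB_new <- A %*% B_new
    P_new <- project_constraint(B_new, constraint, has_intercept)
    f_new <- risk_from_pred(AB_new, Y, epsilon) +
      rho / 2 * sum((B_new - P_new)^2)
    if (mom > 0 && f_new > f_cur + 1e-12) {
      # restart: a plain MM step from B is guaranteed to descend
      m_eff <- 0L
      B_new <- take_step(B, AB)
      AB_new <- A %*% B_new
      P_new <- project_constraint(B_new, constraint, has_intercept)
      f_new <- risk_from_pred(AB_new, Y, epsilon) +
        rho / 2 * sum((B_new - P_new)^2)
    }
    sr <- .shifted_responses(AB_new, Y, epsilon)
    G <- .grad_at(B_new, A, AB_new, sr$Z, sr$outside, P_new, rho, n)
    gn <- sqrt(sum(G^2))
    B_prev <- B; AB_prev <- AB
    B <- B_new; AB <- AB_new; P <- P_new; f_cur <- f_new
    m_eff <- m_eff + 1L
    trace[m] <- f_new
    if (gn <= gtol) { converged <- TRUE; iters <- m; break }
    iters <- m
  }
  list(B = B, AB = AB, P = P, dist = sqrt(sum((B - P)^2)), f = f_cur,
       grad_norm = gn, iters = iters, converged = converged,
       objective_trace = trace[seq_len(iters)])
}

# MM solve of the unpenalized epsilon-insensitive risk (rho = 0 path): each
# surrogate minimization is a minimum-norm least squares solve through the
# thin SVD. Used for dense fits and for the optional post-projection polish.
inner_solve_ls <- function(B_init, A, Y, epsilon, controls, cache = NULL) {
  if (is.null(cache)) cache <- build_svd_cache(A)
  n <- nrow(A)
  gtol <- controls$grad_tol
  if (is.null(gtol)) gtol <- 1e-4 * sqrt(length(B_init))
  B <- B_init
  AB <- A %*% B
  trace <- numeric(controls$max_inner)
  converged <- FALSE
  iters <- 0L
  gn <- Inf
  for (m in seq_len(controls$max_inner)) {
    sr <- .shifted_responses(AB, Y, epsilon)
    G <- .grad_at(B, A, AB, sr$Z, sr$outside, NULL, 0, n)
    gn <- sqrt(sum(G^2))
    if (gn <= gtol) { converged <- TRUE; break }
    B <- cache$V %*% (crossprod(cache$U, sr$Z) / cache$d)
    AB <- A %*% B
    iters <- m
    trace[m] <- risk_from_pred(AB, Y, epsilon)
  }
  list(B = B, AB = AB, f = risk_from_pred(AB, Y, epsilon), grad_norm = gn,
       iters = iters, converged = converged,
       objective_trace = trace[seq_len(iters)])
}

# Post-projection polish: refit the nonzero coordinates of a feasible B by
# unpenalized epsilon-insensitive least squares. The surrogate is
# column-separable given Z, so each class column is refit on its own support
# by a minimum-norm solve; columns sharing a support share the factorization.
polish_fit <- function(B, A, Y, epsilon, controls, has_intercept = FALSE) {
  q <- nrow(B); cc <- ncol(B)
  masks <- lapply(seq_len(cc), function(j) {
    idx <- which(B[, j] != 0)
    if (has_intercept) idx <- sort(unique(c(1L, idx)))
    idx
  })
  keys <- vapply(masks, paste, "", collapse = ",")
  caches <- lapply(unique(keys), function(kk) {
    idx <- masks[[match(kk, keys)]]
    if (length(idx) == 0L) return(NULL)
    build_svd_cache(A[, idx, drop = FALSE])
  })
  names(caches) <- unique(keys)
  gtol <- controls$grad_tol
  if (is.null(gtol)) gtol <- 1e-4 * sqrt(length(B))
  AB <- A %*% B
  n <- nrow(A)
  for (m in seq_len(100L)) {
    sr <- .shifted_responses(AB, Y, epsilon)
    G <- .grad_at(B, A, AB, sr$Z, sr$outside, NULL, 0, n)
    G[B == 0] <- 0
    if (has_intercept) G[1L, ] <- 0
    if (sqrt(sum(G^2)) <= gtol) break
    for (j in seq_len(cc)) {
      idx <- masks[[j]]
      if (length(idx) == 0L) next
      cj <- caches[[keys[j]]]
      B[idx, j] <- cj$V %*% (crossprod(cj$U, sr$Z[, j]) / cj$d)
    }
    AB <- A %*% B
  }
  B
}

#' Annealed proximal distance fit
#'
#' The outer iteration of sparse VDA. For `t = 0, 1, ...` it warm-starts from
#' the previous solution, runs [inner_solve()] at `rho_t`, and records the
#' distance `q_t` from the iterate to the constraint set. Convergence is
#' declared when both the inner gradient condition and one of the distance
#' conditions (`q_t <= delta_d` or `|q_t - q_{t-1}| <= delta_q`) hold --
#' possibly well before `rho` reaches its maximum. The returned coefficient
#' matrix is the final iterate projected onto the constraint set, so it is
#' exactly feasible; `polish = TRUE` additionally refits the selected
#' coordinates by unpenalized epsilon-insensitive least squares (projection
#' alone slightly biases coefficient magnitudes, but the plain projected fit
#' is the reference behavior).
#'
#' @inheritParams inner_solve
#' @param schedule a [vda_schedule()].
#' @param polish refit nonzero coordinates after the final projection?
#' @param B_init optional warm start (defaults to the zero matrix).
#' @return list with the feasible matrix `B_hat`, `support` (overall and per
#'   class), `objective_trace` (per inner iteration, concatenated),
#'   `dist_trace` (`q_t` per annealing step), `rho_trace`, `inner_iters`,
#'   `converged`, and `rho_final`.
#' @export
proximal_distance_fit <- function(A, Y, epsilon, constraint, schedule,
                                  controls, method = c("direct", "steepest"),
                                  cache = NULL, has_intercept = FALSE,
                                  polish = FALSE, B_init = NULL) {
  method <- match.arg(method)
  q <- ncol(A); cc <- ncol(Y)
  if (is.null(B_init)) B_init <- matrix(0, q, cc)
  if (method == "direct" && is.null(cache)) cache <- build_svd_cache(A)
  controls <- resolve_controls(controls, q, cc)

  if (constraint$variant == "none") {
    res <- inner_solve_ls(B_init, A, Y, epsilon, controls, cache = cache)
    sup <- support_of(res$B, has_intercept)
    return(list(B_hat = res$B, support = sup,
                objective_trace = res$objective_trace, dist_trace = 0,
                rho_trace = 0, inner_iters = res$iters,
                converged = res$converged, rho_final = 0))
  }

  B <- B_init
  q_prev <- Inf
  dist_trace <- rho_trace <- numeric(0)
  obj_trace <- numeric(0)
  inner_total <- 0L
  converged <- FALSE
  rho <- schedule$rho0
  for (t in seq_len(schedule$max_outer) - 1L) {
    rho <- min(schedule$rho_max, schedule$rho0 * schedule$mult^t)
    res <- inner_solve(B, A, Y, epsilon, constraint, rho, controls,
                       method = method, cache = cache,
                       has_intercept = has_intercept)
    B <- res$B
    q_t <- res$dist
    dist_trace <- c(dist_trace, q_t)
    rho_trace <- c(rho_trace, rho)
    obj_trace <- c(obj_trace, res$objective_trace)
    inner_total <- inner_total + res$iters
    if (res$converged &&
        (q_t <= controls$dist_tol ||
         abs(q_t - q_prev) <= controls$dist_change_tol)) {
      converged <- TRUE
      break
    }
    q_prev <- q_t
  }
  B_hat <- project_constraint(B, constraint, has_intercept)
  if (polish) {
    B_hat <- polish_fit(B_hat, A, Y, epsilon, controls, has_intercept)
  }
  list(B_hat = B_hat, support = support_of(B_hat, has_intercept),
       objective_trace = obj_trace, dist_trace = dist_trace,
       rho_trace = rho_trace, inner_iters = inner_total,
       converged = converged, rho_final = rho)
}

resolve_controls <- function(controls, q, cc) {
  if (is.null(controls$grad_tol)) controls$grad_tol <- 1e-4 * sqrt(q * cc)
  controls
}
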