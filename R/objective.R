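#' Squared epsilon-insensitive empirical risk
#'
#' The VDA loss
#' \deqn{f(B) = \frac{1}{2n} \sum_i \max(0, \|y_i - B^\top x_i\| - \epsilon)^2,}
#' where `y_i` is the vertex encoding of sample `i`'s class. Residuals inside a
#' Euclidean ball of radius `epsilon` around the class vertex incur no loss;
#' outside the ball the loss is the squared excess distance. `epsilon = 0`
#' gives the ordinary Frobenius least-squares risk.
#'
#' @param B coefficient matrix `q x c` (matching the columns of `A`).
#' @param A design matrix `n x q` (pass an explicit ones column for an
#'   intercept).
#' @param Y one-hot label matrix `n x c`.
#' @param epsilon insensitivity radius, nonnegative. Values below
#'   `sqrt(2)/2` (half the inter-vertex distance) keep the zero-loss balls of
#'   distinct classes disjoint.
#' @return nonnegative scalar.
#' @export
epsilon_risk <- function(B, A, Y, epsilon) {
  stopifnot(epsilon >= 0, nrow(B) == ncol(A), nrow(A) == nrow(Y))
  R <- Y - A %*% B
  rn <- sqrt(rowSums(R^2))
  sum(pmax(rn - epsilon, 0)^2) / (2 * nrow(A))
}

# risk from a precomputed prediction matrix AB (hot path in the solver)
risk_from_pred <- function(AB, Y, epsilon) {
  rn <- sqrt(rowSums((Y - AB)^2))
  sum(pmax(rn - epsilon, 0)^2) / (2 * nrow(Y))
}

#' Shifted responses of the quadratic MM surrogate
#'
#' Distance majorization of the epsilon-insensitive risk at the anchor `B_m`
#' yields an ordinary sum of squares with shifted responses `Z`: for samples
#' whose residual norm is at most `epsilon`, row `i` of `Z` equals the anchor
#' prediction itself (the sample is loss-free and pulled to its own
#' prediction); otherwise
#' \deqn{z_i = w_i y_i + (1 - w_i)\, B_m^\top x_i, \quad
#'       w_i = (\|r_i\| - \epsilon)/\|r_i\| \in (0, 1],}
#' with `r_i` the anchor residual. Residual norms exactly equal to `epsilon`
#' count as inside the ball.
#'
#' @param B_anchor anchor coefficient matrix `B_m`.
#' @param A,Y,epsilon as in [epsilon_risk()].
#' @param AB optional precomputed `A %*% B_anchor`.
#' @return list of class `vda_surrogate` with elements `B_anchor`, `Z`,
#'   `weights` (NA for inside-ball samples), `residual_norms`, `outside`
#'   (logical), and `P` (projection of the anchor; `NULL` until the solver
#'   fills it).
#' @export
surrogate_responses <- function(B_anchor, A, Y, epsilon, AB = NULL) {
  stopifnot(epsilon >= 0)
  if (is.null(AB)) AB <- A %*% B_anchor
  R <- Y - AB
  rn <- sqrt(rowSums(R^2))
  out <- rn > epsilon
  Z <- AB
  w <- rep(NA_real_, length(rn))
  if (any(out)) {
    w[out] <- (rn[out] - epsilon) / rn[out]
    Z[out, ] <- w[out] * Y[out, , drop = FALSE] +
      (1 - w[out]) * AB[out, , drop = FALSE]
  }
  structure(list(B_anchor = B_anchor, Z = Z, weights = w,
                 residual_norms = rn, outside = out, P = NULL),
            class = "vda_surrogate")
}

#' Penalized surrogate value
#'
#' Evaluates the quadratic majorizer
#' `(1/2n) ||Z - A B||_F^2 + (rho/2) ||B - P||_F^2` built at the anchor stored
#' in `state`. `P` is the projection of the anchor onto the constraint set
#' (intercept row, when present, passed through unchanged so it contributes
#' nothing at the anchor).
#'
#' @param B matrix at which to evaluate the surrogate.
#' @param state a [surrogate_responses()] result with `P` filled in.
#' @param A design matrix.
#' @param rho distance-penalty coefficient, nonnegative.
#' @return scalar surrogate value.
#' @export
surrogate_value <- function(B, state, A, rho) {
  if (rho > 0 && is.null(state$P)) stop("surrogate state has no projection 'P'")
  val <- sum((state$Z - A %*% B)^2) / (2 * nrow(A))
  if (rho > 0) val <- val + rho / 2 * sum((B - state$P)^2)
  val
}

#' Distance-penalized VDA objective
#'
#' The objective the proximal distance solver minimizes:
#' `f_rho(B) = epsilon_risk(B) + (rho/2) * dist(B, S)^2`, with the distance
#' computed through the constraint's projection (intercept row excluded).
#'
#' @inheritParams epsilon_risk
#' @param constraint a [vda_constraint()].
#' @param rho penalty coefficient, nonnegative.
#' @param has_intercept is row 1 of `B` an intercept row?
#' @return scalar objective value.
#' @export
penalized_objective <- function(B, A, Y, epsilon, constraint, rho,
                                has_intercept = FALSE) {
  stopifnot(rho >= 0)
  val <- epsilon_risk(B, A, Y, epsilon)
  if (rho > 0) {
    val <- val + rho / 2 * distance_to_set(B, constraint, has_intercept)^2
  }
  val
}

#' Gradient of the penalized surrogate
#'
#' Returns `G = -n^{-1} A^T (Z - A B) + rho (B - P)`. By MM tangency,
#' evaluating at the anchor itself yields the gradient of the penalized
#' objective there, which is how the solver monitors its stopping rule without
#' differentiating the nonsmooth distance term.
#'
#' @inheritParams surrogate_value
#' @param AB optional precomputed `A %*% B`.
#' @return matrix of the same shape as `B`.
#' @export
surrogate_gradient <- function(B, state, A, rho, AB = NULL) {
  if (is.null(AB)) AB <- A %*% B
  D <- state$Z - AB
  # rows of Z equal the anchor prediction inside the ball; at B = anchor those
  # rows vanish, so restrict the crossproduct to the active samples
  act <- if (identical(B, state$B_anchor)) state$outside else rep(TRUE, nrow(A))
  G <- if (any(act)) {
    -crossprod(A[act, , drop = FALSE], D[act, , drop = FALSE]) / nrow(A)
  } else {
    matrix(0, nrow(B), ncol(B))
  }
  if (rho > 0) {
    if (is.null(state$P)) stop("surrogate state has no projection 'P'")
    G <- G + rho * (B - state$P)
  }
  G
}
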