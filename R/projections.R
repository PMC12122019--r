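#' Constraint sets for sparse VDA
#'
#' Describes one of the six constraint sets that sparse VDA can impose on the
#' slope matrix `B` (`p x c`, intercept row excluded):
#'
#' * `"row"` -- at most `k` nonzero rows (shared support across classes, the
#'   homogeneous l0 constraint, "HomL0");
#' * `"col"` -- at most `k` nonzero entries per column (class-specific
#'   supports, the heterogeneous l0 constraint, "HetL0");
#' * `"global"` -- at most `k` nonzero entries overall;
#' * `"l1"`, `"l1row"`, `"l1col"` -- the convex analogues: the whole matrix,
#'   each row, or each column restricted to an l1 ball of radius `lambda`;
#' * `"none"` -- unconstrained (used for dense reference fits).
#'
#' @param variant one of `"row"`, `"col"`, `"global"`, `"l1"`, `"l1row"`,
#'   `"l1col"`, `"none"`.
#' @param k sparsity level for the l0 variants. For `"col"` a single value is
#'   shared by all columns, or a vector of length `c` gives a per-column limit.
#' @param lambda l1-ball radius for the l1 variants.
#' @return object of class `vda_constraint`.
#' @export
#' @examples
#' vda_constraint("row", k = 30)
vda_constraint <- function(variant = c("row", "col", "global",
                                       "l1", "l1row", "l1col", "none"),
                           k = NULL, lambda = NULL) {
  variant <- match.arg(variant)
  if (variant %in% c("row", "col", "global")) {
    if (is.null(k) || any(k < 1) || any(k != round(k))) {
      stop("l0 constraints need a positive integer 'k'")
    }
    k <- as.integer(k)
  }
  if (variant %in% c("l1", "l1row", "l1col")) {
    if (is.null(lambda) || lambda <= 0) stop("l1 constraints need 'lambda' > 0")
  }
  structure(list(variant = variant, k = k, lambda = lambda),
            class = "vda_constraint")
}

#' @export
print.vda_constraint <- function(x, ...) {
  lab <- switch(x$variant,
    row = sprintf("row-sparse (HomL0), k = %s", paste(x$k, collapse = ",")),
    col = sprintf("column-sparse (HetL0), k = %s", paste(x$k, collapse = ",")),
    global = sprintf("globally sparse, k = %d", x$k),
    l1 = sprintf("l1 ball, lambda = %g", x$lambda),
    l1row = sprintf("per-row l1 balls, lambda = %g", x$lambda),
    l1col = sprintf("per-column l1 balls, lambda = %g", x$lambda),
    none = "none (dense)")
  cat("VDA constraint:", lab, "\n")
  invisible(x)
}

#' Project onto the row-sparsity set
#'
#' Euclidean projection of a `p x c` matrix onto the set of matrices with at
#' most `k` nonzero rows: rows are ranked by Euclidean norm, the top `k` kept
#' verbatim and the rest zeroed. Ties at the boundary are broken in favor of
#' the lower row index (the projection is nonunique in principle; a
#' deterministic selection keeps the solver reproducible).
#'
#' @param B numeric matrix.
#' @param k number of rows to keep, `1 <= k <= nrow(B)`.
#' @return matrix of the same shape.
#' @export
project_row_sparse <- function(B, k) {
  p <- nrow(B)
  if (k < 1 || k > p) stop("'k' must satisfy 1 <= k <= nrow(B)")
  if (k == p) return(B)
  nrm <- rowSums(B^2)
  keep <- order(nrm, decreasing = TRUE)[seq_len(k)]  # stable: ties -> low index
  out <- matrix(0, p, ncol(B), dimnames = dimnames(B))
  out[keep, ] <- B[keep, , drop = FALSE]
  out
}

#' Project onto the column-wise sparsity set
#'
#' Independently for each column, keeps the `k` largest-magnitude entries and
#' zeroes the rest (ties to the lower row index). `k` may be a vector giving a
#' separate budget per column.
#'
#' @inheritParams project_row_sparse
#' @param k entries kept per column; scalar or vector of length `ncol(B)`.
#' @export
project_col_sparse <- function(B, k) {
  p <- nrow(B)
  k <- rep_len(as.integer(k), ncol(B))
  if (any(k < 1) || any(k > p)) stop("'k' must satisfy 1 <= k <= nrow(B)")
  out <- matrix(0, p, ncol(B), dimnames = dimnames(B))
  for (j in seq_len(ncol(B))) {
    if (k[j] == p) { out[, j] <- B[, j]; next }
    keep <- order(abs(B[, j]), decreasing = TRUE)[seq_len(k[j])]
    out[keep, j] <- B[keep, j]
  }
  out
}

#' Project onto the global sparsity set
#'
#' Keeps the `k` largest-magnitude entries of the whole matrix (column-major
#' ties broken toward earlier positions) and zeroes the rest.
#'
#' @inheritParams project_row_sparse
#' @param k entries kept overall, `1 <= k <= length(B)`.
#' @export
project_global_sparse <- function(B, k) {
  if (k < 1 || k > length(B)) stop("'k' must satisfy 1 <= k <= length(B)")
  if (k == length(B)) return(B)
  keep <- order(abs(B), decreasing = TRUE)[seq_len(k)]
  out <- B
  out[-keep] <- 0
  out
}

# Euclidean projection of a vector onto the l1 ball of radius lambda
# (sort-and-threshold; exact soft threshold with data-dependent theta).
proj_l1_vec <- function(v, lambda) {
  a <- abs(v)
  if (sum(a) <= lambda) return(v)
  u <- sort(a, decreasing = TRUE)
  css <- cumsum(u)
  j <- seq_along(u)
  rho <- max(j[u > (css - lambda) / j])
  theta <- (css[rho] - lambda) / rho
  sign(v) * pmax(a - theta, 0)
}

#' Project onto l1 balls
#'
#' Euclidean projection onto the l1 ball of radius `lambda`, applied to the
#' flattened matrix (`variant = "global"`), to each row (`"row"`), or to each
#' column (`"col"`). Inputs already inside the ball are returned unchanged.
#'
#' @param B numeric matrix or vector.
#' @param lambda ball radius, positive.
#' @param variant scope of the ball.
#' @return object of the same shape as `B`.
#' @export
project_l1 <- function(B, lambda, variant = c("global", "row", "col")) {
  variant <- match.arg(variant)
  if (lambda <= 0) stop("'lambda' must be positive")
  if (is.null(dim(B))) return(proj_l1_vec(B, lambda))
  out <- B
  if (variant == "global") {
    out[] <- proj_l1_vec(as.vector(B), lambda)
  } else if (variant == "row") {
    for (i in seq_len(nrow(B))) out[i, ] <- proj_l1_vec(B[i, ], lambda)
  } else {
    for (j in seq_len(ncol(B))) out[, j] <- proj_l1_vec(B[, j], lambda)
  }
  out
}

#' Project a slope matrix onto a constraint set
#'
#' Dispatches on the constraint variant. When `has_intercept` is `TRUE` the
#' first row of `B` holds intercepts and is passed through unchanged; only the
#' slope rows are projected. (Distances to the constraint set consequently
#' never involve the intercept row.)
#'
#' @param B slope matrix (`p x c`, or `(p + 1) x c` with intercept row first).
#' @param constraint a [vda_constraint()].
#' @param has_intercept is row 1 an intercept row exempt from the constraint?
#' @return projected matrix, same shape as `B`.
#' @export
project_constraint <- function(B, constraint, has_intercept = FALSE) {
  if (has_intercept) {
    inner <- project_constraint(B[-1L, , drop = FALSE], constraint, FALSE)
    return(rbind(B[1L, , drop = FALSE], inner))
  }
  switch(constraint$variant,
    row = project_row_sparse(B, constraint$k),
    col = project_col_sparse(B, constraint$k),
    global = project_global_sparse(B, constraint$k),
    l1 = project_l1(B, constraint$lambda, "global"),
    l1row = project_l1(B, constraint$lambda, "row"),
    l1col = project_l1(B, constraint$lambda, "col"),
    none = B)
}

#' Distance from a slope matrix to a constraint set
#'
#' Frobenius distance `||B - P_S(B)||_F`, the quantity the annealed proximal
#' distance solver drives to zero. For the row-sparsity set this equals the
#' square root of the summed squared norms of the dropped rows. The intercept
#' row, when present, is excluded.
#'
#' @inheritParams project_constraint
#' @return nonnegative scalar.
#' @export
distance_to_set <- function(B, constraint, has_intercept = FALSE) {
  if (has_intercept) B <- B[-1L, , drop = FALSE]
  P <- project_constraint(B, constraint, FALSE)
  sqrt(sum((B - P)^2))
}

# Index sets of selected features implied by a feasible slope matrix.
# Returns list(overall = integer vector, per_class = list of integer vectors).
support_of <- function(B, has_intercept = FALSE) {
  if (has_intercept) B <- B[-1L, , drop = FALSE]
  per_class <- lapply(seq_len(ncol(B)), function(j) which(B[, j] != 0))
  list(overall = which(rowSums(B != 0) > 0), per_class = per_class)
}
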