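#' Fit a (sparse) vertex discriminant classifier
#'
#' Trains linear or radial-basis-kernel VDA by minimizing the squared
#' epsilon-insensitive risk, optionally subject to an l0 or l1 constraint
#' enforced through an annealed distance penalty. Class labels are encoded as
#' simplex vertices (standard basis vectors of `R^c`); prediction assigns the
#' nearest vertex.
#'
#' For the kernel model the design is the `n x n` Gram matrix, each
#' coefficient row belongs to one training instance, and row sparsity selects
#' at most `k` "avatars" (the analogue of support vectors); the column-sparse
#' constraint selects avatars specific to each class. The model stays linear
#' in its parameters, so the same solver applies unchanged.
#'
#' @param x feature matrix (`n x p`), no intercept column.
#' @param y vector of `n` class labels.
#' @param constraint a [vda_constraint()]; the default fits the dense model.
#' @param epsilon insensitivity radius; the default 0.5 sits below
#'   `sqrt(2)/2`, half the distance between any two vertices.
#' @param kernel `NULL` for the linear model or `"rbf"` for the Gaussian
#'   kernel `exp(-gamma * ||u - v||^2)`.
#' @param gamma kernel scale; defaults to the median heuristic
#'   (1 / median pairwise squared distance) when a kernel is requested.
#' @param standardize z-score each feature column using training statistics?
#'   Recommended: the loss and `epsilon` are scale-sensitive.
#' @param intercept include an intercept row (exempt from constraints)?
#' @param schedule a [vda_schedule()].
#' @param controls a [vda_controls()].
#' @param method `"direct"` (thin SVD + Woodbury updates) or `"steepest"`
#'   (SVD-free exact-step gradient descent, for very large problems).
#' @param polish refit selected coordinates after the final projection
#'   (`FALSE` gives the plain projected solution).
#' @param class_order optional fixed ordering of the class labels.
#' @param B_init optional warm start.
#' @param svd_cache optional precomputed [build_svd_cache()] of the internal
#'   design matrix (reused across hyperparameters during cross-validation).
#' @return object of class `vda_fit` (and `vda_kernel_fit` for kernel models):
#'   coefficients `B` (`(p+1) x c` on the standardized scale, intercept row
#'   first), `support`, class order, traces, and convergence information.
#' @seealso [predict.vda_fit()], [vda_cv()]
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60 * 5), 60, 5)
#' y <- ifelse(x[, 1] - x[, 2] > 0, "a", "b")
#' fit <- vda_fit(x, y, vda_constraint("row", k = 2))
#' fit$support$overall
vda_fit <- function(x, y, constraint = vda_constraint("none"),
                    epsilon = 0.5, kernel = NULL, gamma = NULL,
                    standardize = TRUE, intercept = TRUE,
                    schedule = vda_schedule(), controls = vda_controls(),
                    method = c("direct", "steepest"), polish = FALSE,
                    class_order = NULL, B_init = NULL, svd_cache = NULL) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (anyNA(x)) stop("'x' must not contain missing values")
  if (nrow(x) != length(y)) stop("nrow(x) must match length(y)")
  enc <- encode_labels(y, class_order)
  std <- if (standardize) standardize_fit(x) else NULL
  xs <- if (standardize) standardize_apply(x, std) else x

  if (!is.null(kernel)) {
    kernel <- match.arg(kernel, "rbf")
    if (is.null(gamma)) gamma <- median_heuristic_gamma(xs)
    if (constraint$variant %in% c("row", "col", "global") &&
        max(constraint$k) > nrow(xs)) {
      stop("kernel constraint 'k' cannot exceed the number of samples")
    }
    base <- rbf_kernel(xs, xs, gamma)
  } else {
    base <- xs
  }
  A <- if (intercept) cbind(1, base) else base
  if (method == "direct" && is.null(svd_cache)) svd_cache <- build_svd_cache(A)

  fit <- proximal_distance_fit(A, enc$Y, epsilon, constraint, schedule,
                               controls, method = method, cache = svd_cache,
                               has_intercept = intercept, polish = polish,
                               B_init = B_init)
  out <- list(B = fit$B_hat, support = fit$support,
              class_order = enc$class_order, c = enc$c,
              epsilon = epsilon, constraint = constraint,
              has_intercept = intercept, standardize = standardize,
              center = std$center, scale = std$scale,
              kernel = kernel, gamma = gamma,
              x_train = if (!is.null(kernel)) xs else NULL,
              avatars = if (!is.null(kernel)) fit$support$overall else NULL,
              objective_trace = fit$objective_trace,
              dist_trace = fit$dist_trace, rho_trace = fit$rho_trace,
              inner_iters = fit$inner_iters,
              converged = fit$converged, rho_final = fit$rho_final)
  class(out) <- c(if (!is.null(kernel)) "vda_kernel_fit", "vda_fit")
  out
}

#' Predict classes or vertex-space scores from a VDA fit
#'
#' @param object a [vda_fit()] result.
#' @param newx feature matrix with the training feature count.
#' @param type `"class"` for labels, `"vertex"` for the raw `m x c` linear
#'   predictions.
#' @param ... unused.
#' @return labels or a prediction matrix.
#' @export
predict.vda_fit <- function(object, newx,
                            type = c("class", "vertex"), ...) {
  type <- match.arg(type)
  newx <- as.matrix(newx)
  if (!is.null(object$kernel)) {
    if (ncol(newx) != ncol(object$x_train)) stop("feature count mismatch")
    xs <- if (object$standardize) standardize_apply(newx, object) else newx
    av <- object$avatars
    V <- matrix(0, nrow(newx), object$c)
    if (length(av) > 0L) {
      W <- rbf_kernel(xs, object$x_train[av, , drop = FALSE], object$gamma)
      V <- W %*% object$B[1L + av, , drop = FALSE]
    }
    if (object$has_intercept) V <- sweep(V, 2L, object$B[1L, ], "+")
  } else {
    p <- nrow(object$B) - as.integer(object$has_intercept)
    if (ncol(newx) != p) stop("feature count mismatch")
    xs <- if (object$standardize) standardize_apply(newx, object) else newx
    V <- predict_vertices(object$B, xs, object$has_intercept)
  }
  if (type == "vertex") V else classify_vertices(V, object$class_order)
}

#' @export
print.vda_fit <- function(x, ...) {
  kind <- if (!is.null(x$kernel)) {
    sprintf("kernel (rbf, gamma = %.4g)", x$gamma)
  } else "linear"
  cat(sprintf("Sparse VDA fit (%s), %d classes\n", kind, x$c))
  print(x$constraint)
  sel <- length(x$support$overall)
  what <- if (!is.null(x$kernel)) "avatars" else "features"
  cat(sprintf("epsilon = %g; %d %s selected; converged: %s (rho_final = %g)\n",
              x$epsilon, sel, what, x$converged, x$rho_final))
  invisible(x)
}

#' @export
coef.vda_fit <- function(object, ...) object$B

#' Radial basis function (Gaussian) kernel matrix
#'
#' Entry `(i, j)` is `exp(-gamma * ||x1_i - x2_j||^2)`. With `X1 = X2` the
#' matrix is symmetric positive semidefinite with unit diagonal.
#'
#' @param X1,X2 matrices with matching column counts.
#' @param gamma inverse squared length-scale, positive.
#' @return `nrow(X1) x nrow(X2)` kernel matrix.
#' @export
rbf_kernel <- function(X1, X2, gamma) {
  stopifnot(gamma > 0, ncol(X1) == ncol(X2))
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

# median heuristic: gamma = 1 / median pairwise squared distance (on a
# subsample for large n)
median_heuristic_gamma <- function(X, max_n = 500L) {
  n <- nrow(X)
  if (n > max_n) X <- X[seq(1L, n, length.out = max_n), , drop = FALSE]
  d2 <- stats::dist(X)^2
  m <- stats::median(d2)
  if (!is.finite(m) || m <= 0) 1 else 1 / m
}
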