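#' Encode class labels as simplex vertices
#'
#' Vertex discriminant analysis represents the `c` classes as the `c` standard
#' basis vectors of `R^c` (the vertices of a regular simplex; any two distinct
#' vertices are a distance `sqrt(2)` apart). `encode_labels()` maps a label
#' vector onto the corresponding one-hot matrix `Y`, one vertex per row. The
#' deliberately overparameterized encoding (c dimensions rather than c - 1)
#' keeps one coefficient column per class, which is what makes class-specific
#' variable selection possible downstream.
#'
#' @param labels vector of class identifiers (character, factor, integer, ...).
#' @param class_order optional vector fixing the class-to-column mapping; when
#'   omitted the sorted distinct labels are used. Every label must occur in
#'   `class_order` when it is supplied.
#'
#' @return An object of class `vda_encoding`: a list with `class_order`, the
#'   class count `c`, and the `n x c` one-hot matrix `Y`.
#' @seealso [decode_vertices()], [classify_vertices()]
#' @export
#' @examples
#' enc <- encode_labels(c("a", "b", "a"))
#' enc$Y
encode_labels <- function(labels, class_order = NULL) {
  if (length(labels) == 0L) stop("'labels' must be nonempty")
  labels <- as.vector(labels)
  if (is.null(class_order)) {
    class_order <- sort(unique(labels))
  } else {
    unseen <- setdiff(unique(labels), class_order)
    if (length(unseen) > 0L) {
      stop("label(s) not in 'class_order': ", paste(unseen, collapse = ", "))
    }
  }
  cc <- length(class_order)
  idx <- match(labels, class_order)
  Y <- matrix(0, nrow = length(labels), ncol = cc)
  Y[cbind(seq_along(idx), idx)] <- 1
  structure(list(class_order = class_order, c = cc, Y = Y),
            class = "vda_encoding")
}

#' Recover class labels from a one-hot vertex matrix
#'
#' Inverse of [encode_labels()]: each row of `Y` must be a standard basis
#' vector; the position of the 1 indexes into `class_order`.
#'
#' @param Y one-hot matrix (`n x c`).
#' @param class_order class identifiers, column `j` of `Y` meaning
#'   `class_order[j]`.
#' @return vector of labels of length `nrow(Y)`.
#' @export
decode_vertices <- function(Y, class_order) {
  stopifnot(ncol(Y) == length(class_order))
  class_order[max.col(Y, ties.method = "first")]
}

#' Linear predictions in vertex space
#'
#' Computes the `m x c` matrix of linear predictions `t(B) %*% x` for each row
#' `x` of `X`. When `B` carries an intercept (its first row), a constant column
#' of ones is implicitly appended to `X`.
#'
#' @param B coefficient matrix, `p x c` or `(p + 1) x c` with intercept row
#'   first.
#' @param X feature matrix `m x p` (no intercept column).
#' @param has_intercept does row 1 of `B` hold intercepts?
#' @return `m x c` matrix of predictions.
#' @export
predict_vertices <- function(B, X, has_intercept = nrow(B) == ncol(X) + 1L) {
  X <- as.matrix(X)
  q <- ncol(X) + as.integer(has_intercept)
  if (nrow(B) != q) {
    stop("dimension mismatch: B has ", nrow(B), " rows but expected ", q)
  }
  if (has_intercept) {
    sweep(X %*% B[-1L, , drop = FALSE], 2L, B[1L, ], "+")
  } else {
    X %*% B
  }
}

#' Nearest-vertex decision rule
#'
#' Assigns each prediction to the class whose vertex (standard basis vector) is
#' closest in Euclidean distance. Because all vertices have unit norm, the
#' nearest vertex is the one indexing the largest prediction coordinate; exact
#' ties are broken in favor of the lowest class index so the rule is
#' deterministic.
#'
#' @param V `m x c` matrix of vertex-space predictions.
#' @param class_order class identifiers for the `c` columns.
#' @return vector of `m` class labels.
#' @export
classify_vertices <- function(V, class_order) {
  stopifnot(ncol(V) == length(class_order))
  if (nrow(V) == 0L) return(class_order[integer(0)])
  class_order[max.col(V, ties.method = "first")]
}

# Fit column means/scales on a training matrix; zero-variance columns get
# scale 1 so standardization never divides by zero.
standardize_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[!is.finite(scl) | scl < .Machine$double.eps] <- 1
  list(center = ctr, scale = scl)
}

standardize_apply <- function(X, std) {
  sweep(sweep(X, 2L, std$center, "-"), 2L, std$scale, "/")
}
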