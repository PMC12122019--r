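#' Gaussian design with Toeplitz (AR(1)) covariance
#'
#' Draws `n` i.i.d. rows from `N(0, Sigma)` with `Sigma[i, j] = corr^|i - j|`.
#' Because this covariance is exactly that of a stationary AR(1) process, the
#' rows are generated by the AR recursion
#' `x_1 = z_1`, `x_j = corr * x_{j-1} + sqrt(1 - corr^2) * z_j`,
#' which is an exact factorization of `Sigma` at `O(np)` cost.
#'
#' @param n,p dimensions.
#' @param corr Toeplitz parameter in `[0, 1)`.
#' @param seed optional integer seed (set before drawing when given).
#' @return `n x p` matrix.
#' @export
toeplitz_gaussian_design <- function(n, p, corr, seed = NULL) {
  if (corr < 0 || corr >= 1) stop("'corr' must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  Z <- matrix(stats::rnorm(n * p), n, p)
  if (corr == 0) return(Z)
  X <- Z
  fac <- sqrt(1 - corr^2)
  for (j in 2:p) X[, j] <- corr * X[, j - 1] + fac * Z[, j]
  X
}

#' Draw a ground-truth slope matrix with known support
#'
#' Homogeneous regime: exactly `k_star` rows (chosen uniformly) are nonzero
#' and shared by all classes; their entries are i.i.d. uniform on `{-1, 1}`,
#' so every informative feature is active in every class. Heterogeneous
#' regime: the `k_star` informative features are split into `c` disjoint
#' per-class groups of size `k_star / c`; column `l` carries `{-1, 1}` entries
#' on its own group and zeros elsewhere. The submatrix of informative rows is
#' guaranteed full column rank (resampled otherwise), as required by the shift
#' construction.
#'
#' @param p,c dimensions of the slope matrix.
#' @param k_star total number of informative features; the heterogeneous
#'   regime requires `c` to divide `k_star`.
#' @param regime `"homogeneous"` or `"heterogeneous"`.
#' @param seed optional integer seed.
#' @return list with `B_star` (`p x c`), `support` (sorted indices), and
#'   `per_class_support` (list of `c` index vectors; in the homogeneous regime
#'   every class shares the full support).
#' @export
sample_true_slopes <- function(p, c, k_star,
                               regime = c("homogeneous", "heterogeneous"),
                               seed = NULL) {
  regime <- match.arg(regime)
  if (k_star > p) stop("'k_star' cannot exceed 'p'")
  if (regime == "heterogeneous" && k_star %% c != 0) {
    stop("heterogeneous regime requires c to divide k_star")
  }
  if (regime == "homogeneous" && k_star < c) {
    stop("homogeneous regime requires k_star >= c for a full-rank support")
  }
  if (!is.null(seed)) set.seed(seed)
  for (try in seq_len(100L)) {
    B <- matrix(0, p, c)
    rows <- sort(sample.int(p, k_star))
    if (regime == "homogeneous") {
      B[rows, ] <- sample(c(-1, 1), k_star * c, replace = TRUE)
      per_class <- rep(list(rows), c)
    } else {
      groups <- split(sample(rows), rep(seq_len(c), each = k_star / c))
      per_class <- lapply(groups, sort)
      for (l in seq_len(c)) {
        B[per_class[[l]], l] <- sample(c(-1, 1), k_star / c, replace = TRUE)
      }
    }
    if (qr(B[rows, , drop = FALSE])$rank == c) {
      return(list(B_star = B, support = rows, per_class_support = per_class))
    }
  }
  stop("could not sample a full-column-rank slope matrix")
}

#' Assign labels by the nearest-vertex rule
#'
#' Labels each sample with the class whose vertex is closest to
#' `t(B_star) %*% x`; this is the same decision rule the classifier uses.
#'
#' @param X design matrix (`n x p`).
#' @param B_star slope matrix (`p x c`), not all zero.
#' @return integer labels in `1..c`.
#' @export
assign_labels <- function(X, B_star) {
  if (all(B_star == 0)) {
    stop("'B_star' is identically zero: all vertices tie (degenerate)")
  }
  classify_vertices(X %*% B_star, seq_len(ncol(B_star)))
}

#' Noise variance from a target signal-to-noise ratio
#'
#' `sigma^2 = mean_j Var(Y[, j]) / SNR`, with column variances taken
#' empirically over the samples of the one-hot label matrix.
#'
#' @param Y one-hot label matrix.
#' @param snr positive signal-to-noise ratio.
#' @return scalar noise variance.
#' @export
noise_sigma_from_snr <- function(Y, snr) {
  stopifnot(snr > 0)
  v <- mean(apply(Y, 2L, stats::var))
  if (v == 0) warning("labels are constant: noise variance is 0 (degenerate)")
  v / snr
}

#' Sparse shift matrix aligning predictions with labels
#'
#' The raw linear prediction `t(B_star) %*% x` has mean zero, so labels
#' assigned by the nearest-vertex rule are not yet reflected in the design.
#' The remedy is a shift matrix `S`, supported on the informative columns `J`,
#' solving `S[, J] %*% B_star[J, ] = Y - X %*% B_star - E`; afterwards
#' `(X + S) %*% B_star + E = Y` holds exactly. Among the solutions the
#' minimum-Frobenius-norm one is used:
#' `S[, J] = M %*% solve(crossprod(B_J)) %*% t(B_J)`.
#'
#' @param X design (`n x p`).
#' @param B_star slope matrix with full-column-rank informative submatrix.
#' @param Y one-hot labels (`n x c`).
#' @param E noise matrix (`n x c`).
#' @param support informative row indices `J`.
#' @return list with `X_shifted = X + S` and the shift matrix `S`.
#' @export
apply_shift <- function(X, B_star, Y, E, support) {
  BJ <- B_star[support, , drop = FALSE]
  G <- crossprod(BJ)
  if (qr(G)$rank < ncol(BJ)) {
    stop("B_star[J, ] is column-rank deficient; resample the slope matrix")
  }
  M <- Y - X %*% B_star - E
  SJ <- M %*% solve(G, t(BJ))
  S <- matrix(0, nrow(X), ncol(X))
  S[, support] <- SJ
  list(X_shifted = X + S, shift = S)
}

#' Simulate a sparse multiclass classification problem
#'
#' Full generator used by the support-recovery benchmarks: a Toeplitz Gaussian
#' design, a `{-1, 0, 1}` ground-truth slope matrix with `k_star` informative
#' features (shared or class-specific), labels by the nearest-vertex rule,
#' Gaussian noise calibrated to the requested signal-to-noise ratio, and a
#' sparse shift matrix that makes `(X + S) B_star + E = Y` hold exactly. An
#' independent test set of `n_test` samples is produced by the same mechanism
#' with fresh randomness (the training shift has one row per training sample,
#' so it cannot be reused).
#'
#' @param n training samples.
#' @param p features.
#' @param c classes.
#' @param k_star total informative features.
#' @param toeplitz_corr Toeplitz covariance parameter in `[0, 1)`.
#' @param snr signal-to-noise ratio used to calibrate the noise variance.
#' @param regime `"homogeneous"` (shared support) or `"heterogeneous"`
#'   (disjoint per-class supports of size `k_star / c`).
#' @param n_test independent test samples (default 1000).
#' @param seed integer seed; the whole draw is reproducible from it.
#' @return list of class `vda_sim` with `x_train`, `y_train`, `x_test`,
#'   `y_test`, and `truth` (slope matrix `B_star`, `support`,
#'   `per_class_support`, `sigma2`, the training `noise` and `shift`
#'   matrices, and the scenario parameters).
#' @export
simulate_classification <- function(n, p, c, k_star, toeplitz_corr, snr,
                                    regime = c("homogeneous",
                                               "heterogeneous"),
                                    n_test = 1000L, seed = NULL) {
  regime <- match.arg(regime)
  if (!is.null(seed)) set.seed(seed)
  truth <- sample_true_slopes(p, c, k_star, regime)
  gen <- function(m) {
    X <- toeplitz_gaussian_design(m, p, toeplitz_corr)
    lab <- assign_labels(X, truth$B_star)
    Y <- encode_labels(lab, seq_len(c))$Y
    sigma2 <- noise_sigma_from_snr(Y, snr)
    E <- matrix(stats::rnorm(m * c, sd = sqrt(sigma2)), m, c)
    sh <- apply_shift(X, truth$B_star, Y, E, truth$support)
    list(X = sh$X_shifted, y = lab, sigma2 = sigma2, E = E, S = sh$shift)
  }
  tr <- gen(n)
  te <- gen(n_test)
  structure(list(
    x_train = tr$X, y_train = tr$y, x_test = te$X, y_test = te$y,
    truth = list(B_star = truth$B_star, support = truth$support,
                 per_class_support = truth$per_class_support,
                 sigma2 = tr$sigma2, noise = tr$E, shift = tr$S,
                 n = n, p = p, c = c, k_star = k_star,
                 toeplitz_corr = toeplitz_corr, snr = snr, regime = regime)),
    class = "vda_sim")
}

#' Support-recovery metrics
#'
#' True positive rate `|est ∩ true| / |true|` and positive predictive value
#' `|est ∩ true| / |est|` for a selected feature set. When both sets are empty
#' the PPV is 1 by convention; an empty estimate against a nonempty truth
#' scores 0. Given per-class supports (heterogeneous selection), metrics are
#' computed within each class and averaged.
#'
#' @param estimated integer vector of selected indices, or a list of per-class
#'   vectors.
#' @param truth integer vector of true indices, or a list of per-class
#'   vectors matching `estimated`.
#' @return named vector `c(tpr, ppv)`.
#' @export
support_metrics <- function(estimated, truth) {
  one <- function(est, tru) {
    hits <- length(intersect(est, tru))
    tpr <- if (length(tru) == 0L) 1 else hits / length(tru)
    ppv <- if (length(est) == 0L) {
      if (length(tru) == 0L) 1 else 0
    } else hits / length(est)
    c(tpr = tpr, ppv = ppv)
  }
  if (is.list(estimated) || is.list(truth)) {
    stopifnot(is.list(estimated), is.list(truth),
              length(estimated) == length(truth))
    rowMeans(mapply(one, estimated, truth))
  } else {
    one(estimated, truth)
  }
}

#' Two-dimensional nonlinear toy datasets
#'
#' Constructions used to exercise kernel VDA:
#' * `"circles"` -- two concentric rings (radii 1 and 2 with small radial
#'   noise); labels are flipped with probability `flip`, so the irreducible
#'   (Bayes) error equals `flip` exactly by construction (20% at the default).
#' * `"clouds"` -- `c` Gaussian blobs of unit variance centered on a circle of
#'   radius 3.
#' * `"spirals"` -- `c` Archimedean spiral arms with angular offsets and
#'   Gaussian coordinate noise (`noise = 0.3`; larger values give the harder
#'   variant).
#'
#' @param name one of `"circles"`, `"clouds"`, `"spirals"`.
#' @param n total samples.
#' @param c class count (`clouds`/`spirals`; circles is binary).
#' @param flip label-flip probability for `circles`.
#' @param noise coordinate noise for `spirals`; radial noise for `circles`.
#' @param seed optional integer seed.
#' @return list with `x` (`n x 2`) and integer labels `y`.
#' @export
toy_nonlinear <- function(name = c("circles", "clouds", "spirals"),
                          n = 500L, c = 3L, flip = 0.20, noise = 0.3,
                          seed = NULL) {
  name <- match.arg(name)
  if (!is.null(seed)) set.seed(seed)
  if (name == "circles") {
    y <- sample(1:2, n, replace = TRUE)
    r <- c(1, 2)[y] + stats::rnorm(n, sd = min(noise, 0.1))
    th <- stats::runif(n, 0, 2 * pi)
    x <- cbind(r * cos(th), r * sin(th))
    flipped <- stats::runif(n) < flip
    y[flipped] <- 3L - y[flipped]
    return(list(x = x, y = y))
  }
  y <- sample(seq_len(c), n, replace = TRUE)
  if (name == "clouds") {
    ang <- 2 * pi * (y - 1) / c
    x <- cbind(3 * cos(ang), 3 * sin(ang)) + matrix(stats::rnorm(2 * n), n, 2)
    return(list(x = x, y = y))
  }
  th <- stats::runif(n, pi / 4, 4 * pi)
  off <- 2 * pi * (y - 1) / c
  r <- th / (2 * pi)
  x <- cbind(r * cos(th + off), r * sin(th + off)) +
    matrix(stats::rnorm(2 * n, sd = noise / 3), n, 2)
  list(x = x, y = y)
}
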