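# Brute-force oracles kept deliberately independent of the package internals.

# exhaustive projection onto matrices with at most k nonzero rows
bf_project_rows <- function(B, k) {
  p <- nrow(B)
  best <- NULL
  bestd <- Inf
  for (keep in utils::combn(p, k, simplify = FALSE)) {
    C <- matrix(0, p, ncol(B))
    C[keep, ] <- B[keep, , drop = FALSE]
    d <- sum((B - C)^2)
    if (d < bestd - 1e-15) { bestd <- d; best <- C }
  }
  list(P = best, dist2 = bestd)
}

# exhaustive projection keeping k entries of a vector
bf_project_vec <- function(v, k) {
  best <- NULL
  bestd <- Inf
  for (keep in utils::combn(length(v), k, simplify = FALSE)) {
    w <- numeric(length(v))
    w[keep] <- v[keep]
    d <- sum((v - w)^2)
    if (d < bestd - 1e-15) { bestd <- d; best <- w }
  }
  list(P = best, dist2 = bestd)
}

# nearest-vertex classification via an explicit distance table
bf_classify <- function(V, class_order) {
  cc <- length(class_order)
  out <- integer(nrow(V))
  for (i in seq_len(nrow(V))) {
    d <- vapply(seq_len(cc), function(j) {
      e <- numeric(cc); e[j] <- 1
      sum((V[i, ] - e)^2)
    }, 0)
    out[i] <- which(d == min(d))[1]   # first index wins ties
  }
  class_order[out]
}

# central finite-difference gradient of a scalar function of a matrix
fd_gradient <- function(fn, B, h = 1e-6) {
  G <- B
  for (i in seq_along(B)) {
    Bp <- B; Bm <- B
    Bp[i] <- B[i] + h
    Bm[i] <- B[i] - h
    G[i] <- (fn(Bp) - fn(Bm)) / (2 * h)
  }
  G
}

# small random VDA problem for solver tests
random_problem <- function(n = 25, p = 6, cc = 3, seed = 1) {
  set.seed(seed)
  A <- cbind(1, matrix(rnorm(n * p), n, p))
  y <- sample(seq_len(cc), n, replace = TRUE)
  Y <- encode_labels(y, seq_len(cc))$Y
  list(A = A, Y = Y, y = y, q = p + 1L, cc = cc)
}
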