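#' Read a delimited dataset with a label column
#'
#' Loads a CSV/TSV file with a header row, extracts the label column, and
#' validates that every remaining cell is numeric (errors name the offending
#' row and column).
#'
#' @param path file path; the delimiter is inferred from the extension
#'   (`.tsv`/`.txt` means tab) unless `delimiter` overrides it.
#' @param label_column name of the class label column.
#' @param delimiter optional explicit field separator.
#' @return list with the numeric feature matrix `x` and the label vector `y`.
#' @export
read_dataset <- function(path, label_column, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t"
                 else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!label_column %in% names(df)) {
    stop("label column '", label_column, "' not found in ", path)
  }
  y <- df[[label_column]]
  feats <- df[setdiff(names(df), label_column)]
  for (j in seq_along(feats)) {
    v <- feats[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad) > 0L) {
        stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                     v[bad[1]], bad[1], names(feats)[j]))
      }
      feats[[j]] <- num
    }
  }
  x <- as.matrix(feats)
  if (anyNA(x)) stop("missing values in feature columns of ", path)
  list(x = x, y = y)
}

#' Write a dataset to a delimited file
#'
#' Features plus a label column, with numbers at 17 significant digits so a
#' read/write round trip is exact.
#'
#' @param x feature matrix.
#' @param y labels.
#' @param path output path (`.tsv` extension selects tabs).
#' @param label_column name for the label column.
#' @export
write_dataset <- function(x, y, path, label_column = "class") {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  df <- as.data.frame(apply(x, 2L, format, digits = 17, trim = TRUE,
                            scientific = FALSE))
  df[[label_column]] <- y
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

fmt17 <- function(v) format(v, digits = 17, trim = TRUE)

#' Serialize a fit, CV result, or stability report
#'
#' Writes delimited tables plus a JSON manifest into `outdir`:
#' * `vda_fit`: `coefficients.tsv` (feature x class, intercept row labeled),
#'   `support.txt`, `manifest.json` (hyperparameters, convergence, traces);
#' * `vda_cv`: additionally `cv_results.tsv` with the per-fold score grids;
#' * `vda_stability`: `replicates.tsv`, `selection_frequencies.tsv`, and a
#'   JSON summary.
#' All floating point output uses 17 significant digits so values round-trip.
#'
#' @param object a `vda_fit`, `vda_cv`, or `vda_stability`.
#' @param outdir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_fit <- function(object, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wj <- function(x, f) {
    p <- file.path(outdir, f)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    p
  }
  if (inherits(object, "vda_stability")) {
    p1 <- file.path(outdir, "replicates.tsv")
    utils::write.table(object$replicates, p1, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    freq <- data.frame(feature = object$top_features,
                       count = object$feature_counts[object$top_features])
    freq <- cbind(freq, as.data.frame(object$per_class_counts))
    p2 <- file.path(outdir, "selection_frequencies.tsv")
    utils::write.table(freq, p2, sep = "\t", quote = FALSE, row.names = FALSE)
    p3 <- wj(list(n_repeats = object$n_repeats,
                  size_quantiles = as.list(object$size_quantiles),
                  error_quantiles = as.list(object$error_quantiles)),
             "stability_summary.json")
    return(invisible(c(p1, p2, p3)))
  }
  fit <- if (inherits(object, "vda_cv")) object$final_fit else object
  q <- nrow(fit$B)
  rn <- if (fit$has_intercept) {
    c("(intercept)", paste0("feature_", seq_len(q - 1L)))
  } else paste0("feature_", seq_len(q))
  tab <- data.frame(term = rn, apply(fit$B, 2L, fmt17))
  names(tab)[-1L] <- paste0("class_", fit$class_order)
  p1 <- file.path(outdir, "coefficients.tsv")
  utils::write.table(tab, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(outdir, "support.txt")
  writeLines(as.character(fit$support$overall), p2)
  manifest <- list(
    constraint = fit$constraint[c("variant", "k", "lambda")],
    epsilon = fit$epsilon, kernel = fit$kernel, gamma = fit$gamma,
    standardize = fit$standardize, has_intercept = fit$has_intercept,
    class_order = fit$class_order, converged = fit$converged,
    rho_final = fit$rho_final, inner_iters = fit$inner_iters,
    rho_trace = fit$rho_trace, dist_trace = fit$dist_trace)
  if (inherits(object, "vda_cv")) {
    manifest <- c(manifest, list(
      chosen_eps = object$chosen_eps, chosen_gamma = object$chosen_gamma,
      chosen_k = object$chosen_k, test_error = object$test_error,
      n_folds = object$n_folds, seed = object$seed))
    ks <- data.frame(k = object$k_grid, object$k_scores)
    names(ks)[-1L] <- paste0("fold_", seq_len(ncol(object$k_scores)))
    p4 <- file.path(outdir, "cv_results.tsv")
    utils::write.table(ks, p4, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p4)
  }
  p3 <- wj(manifest, "manifest.json")
  invisible(c(p1, p2, p3, paths))
}

#' Reload serialized coefficients
#'
#' Reads a `coefficients.tsv` written by [write_fit()] back into a numeric
#' matrix (intercept row first when present).
#'
#' @param path path to the coefficients table.
#' @return numeric matrix with a `has_intercept` attribute.
#' @export
read_coefficients <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  B <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(B) <- "double"
  attr(B, "has_intercept") <- tab$term[1] == "(intercept)"
  B
}
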