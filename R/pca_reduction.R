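# Covariance-matrix PCA over the screened beat matrix: per-dimension
# centering, sample covariance (n - 1 denominator), eigendecomposition,
# descending sort, and projection.

#' Per-dimension mean, standard deviation and variance
#'
#' Column statistics with the sample (`n - 1`) denominator.
#'
#' @param X numeric matrix with `n >= 2` rows (samples) and `d` columns.
#' @return list with numeric vectors `mean`, `sd`, `var` (length `d`).
#' @export
column_stats <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop_fmt("column_stats: need n >= 2 rows, got %d", nrow(X))
  m <- colMeans(X)
  v <- colSums(sweep(X, 2, m)^2) / (nrow(X) - 1)
  list(mean = m, sd = sqrt(v), var = v)
}

#' Sample covariance matrix
#'
#' `cov(X_i, X_j) = sum((X_i - mean_i) * (X_j - mean_j)) / (n - 1)`;
#' symmetric, with per-dimension variances on the diagonal.
#'
#' @param X numeric matrix, rows = samples.
#' @return `d x d` covariance matrix.
#' @export
covariance_matrix <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop_fmt("covariance_matrix: need n >= 2 rows")
  Xc <- sweep(X, 2, colMeans(X))
  crossprod(Xc) / (nrow(X) - 1)
}

#' Fit a principal-component model
#'
#' Eigendecomposition of the sample covariance matrix, eigenpairs sorted by
#' descending eigenvalue.  Each component's sign is fixed so that its
#' largest-magnitude coordinate is positive (eigenvectors are
#' sign-ambiguous; the convention makes fits reproducible).  Retention:
#' an integer `n_components` keeps that many components; a fraction in
#' `(0, 1)` keeps the smallest count whose cumulative eigenvalue fraction
#' reaches it (default 0.95).
#'
#' @param X numeric matrix (rows = samples) or [beat_matrix()].
#' @param n_components integer count, or variance fraction in `(0, 1)`.
#' @return list of class `pca_model`: `mean`, `eigenvalues` (all `d`,
#'   descending), `components` (`d x n_components`, orthonormal columns),
#'   `n_components`.
#' @export
fit_pca <- function(X, n_components = 0.95) {
  if (inherits(X, "beat_matrix")) X <- X$rows
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop_fmt("fit_pca: non-finite values in input")
  if (nrow(X) < 2) stop_fmt("fit_pca: need n >= 2 rows")
  C <- covariance_matrix(X)
  eig <- eigen(C, symmetric = TRUE)
  vals <- pmax(eig$values, 0)              # clip tiny negative round-off
  vecs <- eig$vectors
  for (j in seq_len(ncol(vecs))) {
    i_max <- which.max(abs(vecs[, j]))
    if (vecs[i_max, j] < 0) vecs[, j] <- -vecs[, j]
  }
  d <- ncol(X)
  if (n_components >= 1) {
    k <- min(as.integer(n_components), d)
  } else {
    total <- sum(vals)
    k <- if (total == 0) 1L else {
      which(cumsum(vals) / total >= n_components)[1]
    }
  }
  structure(list(mean = colMeans(X), eigenvalues = vals,
                 components = vecs[, seq_len(k), drop = FALSE],
                 n_components = k),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  total <- sum(x$eigenvalues)
  frac <- if (total > 0) sum(x$eigenvalues[seq_len(x$n_components)]) / total else NA
  cat(sprintf("<pca_model> %d/%d components (%.1f%% variance)\n",
              x$n_components, length(x$eigenvalues), 100 * frac))
  invisible(x)
}

#' Project data onto a fitted principal-component model
#'
#' Centers rows with the model mean and projects onto the retained
#' components.
#'
#' @param model a `pca_model`.
#' @param X numeric matrix (rows = samples) or [beat_matrix()], width equal
#'   to the model's.
#' @return `n x n_components` score matrix.
#' @export
pca_transform <- function(model, X) {
  stopifnot(inherits(model, "pca_model"))
  if (inherits(X, "beat_matrix")) X <- X$rows
  X <- as.matrix(X)
  if (ncol(X) != length(model$mean)) {
    stop_fmt("pca_transform: input width %d does not match model width %d",
             ncol(X), length(model$mean))
  }
  sweep(X, 2, model$mean) %*% model$components
}

#' Serialize / restore a PCA model as JSON
#'
#' @param model a `pca_model`.
#' @param path file path.
#' @return `read_pca_model()` returns the restored `pca_model`.
#' @export
write_pca_model <- function(model, path) {
  stopifnot(inherits(model, "pca_model"))
  obj <- list(mean = model$mean, eigenvalues = model$eigenvalues,
              components = model$components, n_components = model$n_components)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pca_model
#' @export
read_pca_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = as.numeric(obj$mean),
                 eigenvalues = as.numeric(obj$eigenvalues),
                 components = as.matrix(obj$components),
                 n_components = as.integer(obj$n_components)),
            class = "pca_model")
}
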