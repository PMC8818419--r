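# Gaussian radial-basis-function network: input -> nonlinear hidden layer
# (Gaussian kernels around fixed centers) -> linear output.  Centers sit on
# an evenly spaced per-dimension grid between the training minimum and
# maximum; each unit's width is the mean distance from the training samples
# to its center; output weights come from a one-shot linear least-squares
# fit (default) or an iterative gradient loop with an RMS jump-out
# accuracy.

#' Gaussian radial basis kernel
#'
#' `k(x, c) = exp(-||x - c||^2 / (2 sigma^2))`, a monotone decreasing
#' function of the Euclidean distance, equal to 1 at the center.
#'
#' @param x,center numeric vectors of equal width.
#' @param sigma kernel width, `> 0`.
#' @return value in `(0, 1]`.
#' @export
gaussian_kernel <- function(x, center, sigma) {
  if (sigma <= 0) stop_fmt("gaussian_kernel: sigma must be > 0, got %g", sigma)
  if (length(x) != length(center)) {
    stop_fmt("gaussian_kernel: width mismatch (%d vs %d)",
             length(x), length(center))
  }
  exp(-sum((x - center)^2) / (2 * sigma^2))
}

#' Initialize hidden-unit centers
#'
#' `H` centers on an evenly spaced per-dimension grid between the training
#' minimum and maximum: coordinate `j` of center `h` is
#' `min_j + (h - 1) (max_j - min_j) / (H - 1)`; a single unit sits at the
#' midpoint.  `method = "kmeans"` uses K-means centroids of the training
#' scores instead.
#'
#' @param X training score matrix (rows = samples).
#' @param H number of hidden units.
#' @param method `"grid"` (default) or `"kmeans"`.
#' @param seed RNG seed for the K-means variant.
#' @return `H x d` center matrix.
#' @export
rbf_init_centers <- function(X, H, method = c("grid", "kmeans"), seed = 1L) {
  X <- as.matrix(X)
  method <- match.arg(method)
  if (H < 1) stop_fmt("rbf_init_centers: H must be >= 1")
  if (method == "kmeans") {
    res <- beats_kmeans(X, k = H, seed = seed)
    return(res$centers)
  }
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  if (H == 1) {
    return(matrix((lo + hi) / 2, nrow = 1))
  }
  ctr <- vapply(seq_len(H), function(h) lo + (h - 1) * (hi - lo) / (H - 1),
                numeric(ncol(X)))
  t(matrix(ctr, nrow = ncol(X)))
}

#' Initialize hidden-unit widths
#'
#' Width of unit `j` is the mean Euclidean distance from the training
#' samples to its center, floored at `1e-6` times the global data range so
#' every width stays positive.
#'
#' @param X training score matrix.
#' @param centers `H x d` center matrix.
#' @return numeric vector of `H` positive widths.
#' @export
rbf_init_widths <- function(X, centers) {
  X <- as.matrix(X)
  centers <- as.matrix(centers)
  d2 <- .dist2_to_centers(X, centers)
  w <- colMeans(sqrt(d2))
  rng <- max(X) - min(X)
  floor_w <- 1e-6 * max(rng, 1e-12)
  pmax(w, floor_w)
}

# hidden activation matrix: n x H
.rbf_phi <- function(X, centers, widths) {
  d2 <- .dist2_to_centers(as.matrix(X), centers)
  exp(-sweep(d2, 2, 2 * widths^2, "/"))
}

#' Forward pass of an RBF network
#'
#' `score = bias + sum_j w_j k(x, c_j, sigma_j)`; linear in the output
#' weights.
#'
#' @param model an `rbf_model`.
#' @param X numeric matrix of inputs (rows = samples) or a single vector.
#' @return numeric vector of raw scores.
#' @export
rbf_forward <- function(model, X) {
  stopifnot(inherits(model, "rbf_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  phi <- .rbf_phi(X, model$centers, model$widths)
  as.numeric(phi %*% model$weights + model$bias)
}

#' Root-mean-square error
#'
#' `RMS = sqrt(sum((targets - outputs)^2) / N)` over all entries.
#'
#' @param outputs,targets equal-length numeric vectors.
#' @return non-negative scalar.
#' @export
rms_error <- function(outputs, targets) {
  if (length(outputs) != length(targets)) {
    stop_fmt("rms_error: length mismatch")
  }
  sqrt(sum((targets - outputs)^2) / length(outputs))
}

#' Train an RBF network classifier
#'
#' Centers and widths are initialized with [rbf_init_centers()] and
#' [rbf_init_widths()]; output weights (plus bias) are then fitted to the
#' binary targets (normal = 1, abnormal = 0).
#'
#' * `solver = "least_squares"` (default): one-shot minimum-norm linear
#'   least squares of the targets on the hidden-activation matrix with a
#'   bias column — deterministic and optimal for the linear output layer.
#' * `solver = "gradient"`: epoch loop of full-batch gradient steps on the
#'   squared error, recomputing the training RMS each epoch and stopping
#'   as soon as `RMS <= epsilon` or after `max_epochs`.
#'
#' @param X training score matrix (rows = samples).
#' @param y labels: factor/character `"normal"`/`"abnormal"`, logical
#'   (TRUE = normal), or numeric 1/0 targets.  Both classes must be
#'   present.
#' @param H hidden-unit count (default 10), `H <= nrow(X)`.
#' @param solver `"least_squares"` or `"gradient"`.
#' @param epsilon RMS jump-out accuracy for the gradient loop.
#' @param max_epochs epoch cap for the gradient loop.
#' @param learning_rate gradient step size.
#' @param decision_threshold score threshold for [rbf_predict()].
#' @param center_method passed to [rbf_init_centers()].
#' @param seed RNG seed (gradient initialization / K-means centers).
#' @return list of class `rbf_model`: `centers`, `widths`, `weights`,
#'   `bias`, `decision_threshold`, `rms_trace` (per-epoch RMS; length 1 for
#'   least squares), `solver`.
#' @export
rbf_train <- function(X, y, H = 10, solver = c("least_squares", "gradient"),
                      epsilon = 1e-2, max_epochs = 500, learning_rate = 0.5,
                      decision_threshold = 0.5,
                      center_method = c("grid", "kmeans"), seed = 1L) {
  X <- as.matrix(X)
  solver <- match.arg(solver)
  center_method <- match.arg(center_method)
  targets <- .as_targets(y)
  if (length(targets) != nrow(X)) stop_fmt("rbf_train: %d labels for %d rows",
                                           length(targets), nrow(X))
  if (length(unique(targets)) < 2) {
    stop_fmt("rbf_train: both classes must be present in y")
  }
  if (H > nrow(X)) stop_fmt("rbf_train: H = %d exceeds sample count %d",
                            H, nrow(X))
  centers <- rbf_init_centers(X, H, method = center_method, seed = seed)
  widths <- rbf_init_widths(X, centers)
  phi <- cbind(1, .rbf_phi(X, centers, widths))
  n <- nrow(X)
  if (solver == "least_squares") {
    fit <- qr.coef(qr(phi, LAPACK = TRUE), targets)
    fit[is.na(fit)] <- 0
    w <- fit[-1]
    b <- fit[1]
    rms <- rms_error(as.numeric(phi %*% fit), targets)
    trace <- rms
  } else {
    coef <- with_seed(seed, stats::rnorm(H + 1, sd = 0.1))
    trace <- numeric(0)
    for (epoch in seq_len(max_epochs)) {
      out <- as.numeric(phi %*% coef)
      grad <- crossprod(phi, out - targets) / n
      coef <- coef - learning_rate * as.numeric(grad)
      rms <- rms_error(as.numeric(phi %*% coef), targets)
      trace <- c(trace, rms)
      if (rms <= epsilon) break
    }
    w <- coef[-1]
    b <- coef[1]
  }
  structure(list(centers = centers, widths = widths, weights = w, bias = b,
                 decision_threshold = decision_threshold,
                 rms_trace = trace, solver = solver),
            class = "rbf_model")
}

.as_targets <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    if (!all(y %in% c("normal", "abnormal"))) {
      stop_fmt("rbf targets must be 'normal'/'abnormal'")
    }
    return(as.numeric(y == "normal"))
  }
  if (is.logical(y)) return(as.numeric(y))
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop_fmt("numeric rbf targets must be 0/1")
  y
}

#' @export
print.rbf_model <- function(x, ...) {
  cat(sprintf("<rbf_model> %d hidden units, %d-dim input, %s solver (train RMS %.4g)\n",
              length(x$widths), ncol(x$centers), x$solver,
              utils::tail(x$rms_trace, 1)))
  invisible(x)
}

#' Classify scores with a trained RBF network
#'
#' A sample is `"normal"` when its score reaches the decision threshold
#' (`score >= threshold`), `"abnormal"` otherwise.
#'
#' @param model an `rbf_model`.
#' @param X score matrix (rows = samples).
#' @param threshold override of the model's decision threshold.
#' @return factor with levels `c("normal", "abnormal")`.
#' @export
rbf_predict <- function(model, X, threshold = model$decision_threshold) {
  s <- rbf_forward(model, X)
  factor(ifelse(s >= threshold, "normal", "abnormal"),
         levels = c("normal", "abnormal"))
}

#' Serialize / restore an RBF model as JSON
#'
#' @param model an `rbf_model`.
#' @param path file path.
#' @return `read_rbf_model()` returns the restored `rbf_model`.
#' @export
write_rbf_model <- function(model, path) {
  stopifnot(inherits(model, "rbf_model"))
  obj <- list(centers = model$centers, widths = model$widths,
              weights = model$weights, bias = model$bias,
              decision_threshold = model$decision_threshold,
              solver = model$solver)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_rbf_model
#' @export
read_rbf_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(centers = as.matrix(obj$centers),
                 widths = as.numeric(obj$widths),
                 weights = as.numeric(obj$weights),
                 bias = as.numeric(obj$bias),
                 decision_threshold = as.numeric(obj$decision_threshold),
                 rms_trace = NA_real_, solver = obj$solver),
            class = "rbf_model")
}
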