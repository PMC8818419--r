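# K-means (K = 2) screening of truncated beats.  Lloyd iterations with the
# sum-of-squared-errors criterion J and a delta-J stopping rule; the
# minority cluster is discarded as outlier material.

#' Euclidean distance between two equal-width vectors
#'
#' @param a,b numeric vectors of equal length.
#' @return `sqrt(sum((a - b)^2))`.
#' @export
euclidean_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop_fmt("euclidean_distance: width mismatch (%d vs %d)",
             length(a), length(b))
  }
  sqrt(sum((a - b)^2))
}

# squared distances from every row of X to every center (n x k)
.dist2_to_centers <- function(X, centers) {
  xx <- rowSums(X^2)
  cc <- rowSums(centers^2)
  d2 <- outer(xx, cc, "+") - 2 * X %*% t(centers)
  pmax(d2, 0)
}

#' Lloyd's K-means with a delta-J stopping rule
#'
#' Assigns each row to its nearest center (Euclidean distance), recomputes
#' centers as member means, and accumulates
#' `J = sum over clusters of squared member-to-center distances` (the SSE
#' criterion).  Iteration stops when `|J_prev - J| < delta_j` or after
#' `max_iter` sweeps.  Initial centers are `k` distinct rows drawn
#' uniformly at random under `seed`; `init = "plusplus"` uses k-means++
#' seeding instead.  An emptied cluster is reseeded at the row farthest
#' from its assigned center.
#'
#' @param X numeric matrix (rows = beats) or a [beat_matrix()].
#' @param k number of clusters (default 2).
#' @param delta_j stopping threshold on the change in J; default
#'   `1e-4 * ncol(X)`.
#' @param max_iter iteration cap.
#' @param seed RNG seed for initialization.
#' @param init `"random"` (distinct rows) or `"plusplus"`.
#' @return list of class `cluster_result`: `assignments`, `centers`, `J`,
#'   `iterations`, `J_trace` (J after every sweep), `delta_J_trace`.
#' @export
beats_kmeans <- function(X, k = 2, delta_j = NULL, max_iter = 100,
                         seed = 1L, init = c("random", "plusplus")) {
  if (inherits(X, "beat_matrix")) X <- X$rows
  X <- as.matrix(X)
  init <- match.arg(init)
  n <- nrow(X)
  d <- ncol(X)
  if (is.null(delta_j)) delta_j <- 1e-4 * d
  distinct <- unique(X)
  if (nrow(distinct) < k) {
    stop_fmt("beats_kmeans: only %d distinct rows for k = %d",
             nrow(distinct), k)
  }
  centers <- with_seed(seed, {
    if (init == "random") {
      distinct[sample(nrow(distinct), k), , drop = FALSE]
    } else {
      ctr <- X[sample(n, 1), , drop = FALSE]
      while (nrow(ctr) < k) {
        d2 <- apply(.dist2_to_centers(X, ctr), 1, min)
        if (sum(d2) == 0) {
          ctr <- rbind(ctr, distinct[nrow(ctr) + 1, ])
        } else {
          ctr <- rbind(ctr, X[sample(n, 1, prob = d2), ])
        }
      }
      ctr
    }
  })
  j_prev <- Inf
  j_trace <- numeric(0)
  assignments <- rep(1L, n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- .dist2_to_centers(X, centers)
    assignments <- max.col(-d2, ties.method = "first")
    # empty-cluster repair: reseed at the row farthest from its center
    for (c_id in seq_len(k)) {
      if (!any(assignments == c_id)) {
        far <- which.max(d2[cbind(seq_len(n), assignments)])
        centers[c_id, ] <- X[far, ]
        assignments[far] <- c_id
        d2 <- .dist2_to_centers(X, centers)
      }
    }
    for (c_id in seq_len(k)) {
      centers[c_id, ] <- colMeans(X[assignments == c_id, , drop = FALSE])
    }
    j <- sum(.dist2_to_centers(X, centers)[cbind(seq_len(n), assignments)])
    j_trace <- c(j_trace, j)
    if (is.finite(j_prev) && abs(j_prev - j) < delta_j) break
    if (iter >= max_iter) break
    j_prev <- j
  }
  structure(list(assignments = assignments, centers = centers, J = j,
                 iterations = iter, J_trace = j_trace,
                 delta_J_trace = c(NA_real_, -diff(j_trace))),
            class = "cluster_result")
}

#' Discard the minority cluster
#'
#' For a K = 2 clustering of truncated beats the larger cluster is taken as
#' the retained material and the smaller one discarded as outliers.  On an
#' exact size tie the cluster with the smaller within-cluster J is kept (a
#' warning is raised); if only one cluster is occupied everything is kept,
#' with a warning.
#'
#' @param beats a [beat_matrix()] (or bare matrix) the clustering was run
#'   on.
#' @param result a `cluster_result` with `k = 2`.
#' @return list with elements `kept` and `discarded`, both [beat_matrix()]
#'   (or matrices, matching the input type).
#' @export
screen_minority <- function(beats, result) {
  stopifnot(inherits(result, "cluster_result"))
  if (nrow(result$centers) != 2) {
    stop_fmt("screen_minority: needs a K = 2 clustering")
  }
  asg <- result$assignments
  sizes <- tabulate(asg, nbins = 2)
  if (any(sizes == 0)) {
    warning("screen_minority: single occupied cluster; keeping all beats")
    keep_id <- which(sizes > 0)
  } else if (sizes[1] == sizes[2]) {
    X <- if (inherits(beats, "beat_matrix")) beats$rows else as.matrix(beats)
    wj <- vapply(1:2, function(c_id) {
      mem <- X[asg == c_id, , drop = FALSE]
      sum(sweep(mem, 2, result$centers[c_id, ])^2)
    }, numeric(1))
    warning("screen_minority: exact size tie; keeping the tighter cluster")
    keep_id <- which.min(wj)
  } else {
    keep_id <- which.max(sizes)
  }
  subset_rows <- function(b, sel) {
    if (inherits(b, "beat_matrix")) {
      beat_matrix(b$rows[sel, , drop = FALSE], b$fs,
                  labels = if (is.null(b$labels)) NULL else b$labels[sel],
                  r_index = if (is.null(b$r_index)) NULL else b$r_index[sel])
    } else {
      as.matrix(b)[sel, , drop = FALSE]
    }
  }
  list(kept = subset_rows(beats, asg == keep_id),
       discarded = subset_rows(beats, asg != keep_id))
}
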