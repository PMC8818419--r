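# Brute-force per-sample recursion/convolution oracles for the filter
# cascade.  Intentionally naive: each output sample is computed from the
# defining difference equation with out-of-range indices read as zero.

oracle_lowpass <- function(x) {
  n <- length(x)
  y <- numeric(n)
  at <- function(v, i) if (i >= 1) v[i] else 0
  for (i in seq_len(n)) {
    y[i] <- 2 * at(y, i - 1) - at(y, i - 2) +
      x[i] - 2 * at(x, i - 6) + at(x, i - 12)
  }
  y
}

oracle_highpass <- function(x) {
  n <- length(x)
  at <- function(v, i) if (i >= 1) v[i] else 0
  p <- numeric(n)
  y <- numeric(n)
  for (i in seq_len(n)) {
    p[i] <- at(p, i - 1) + x[i] - at(x, i - 32)
    y[i] <- at(x, i - 16) - p[i] / 32
  }
  y
}

oracle_integrate <- function(x, w) {
  n <- length(x)
  y <- numeric(n)
  for (i in seq_len(n)) {
    y[i] <- sum(x[max(1, i - w + 1):i]) / w
  }
  y
}

# exhaustive search over all 2-partitions: the global SSE optimum on tiny
# instances, the independent oracle for Lloyd's algorithm
best_two_partition_J <- function(X) {
  n <- nrow(X)
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    sel <- bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) != 0L
    a <- X[sel, , drop = FALSE]
    b <- X[!sel, , drop = FALSE]
    j <- sum(sweep(a, 2, colMeans(a))^2) + sum(sweep(b, 2, colMeans(b))^2)
    best <- min(best, j)
  }
  best
}

# small two-group instance of the kind screening sees: a majority cluster
# plus separated outlier material
kmeans_instance <- function(seed) {
  set.seed(1000 + seed)
  n <- sample(6:12, 1)
  n1 <- n %/% 2
  rbind(matrix(rnorm(n1 * 2), n1, 2),
        matrix(rnorm((n - n1) * 2, mean = 4), n - n1, 2))
}
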