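# Shared fixtures: noiseless / default-noise synthesis configs and a
# peak-matching helper used by detector sensitivity tests.

quiet_config <- function(duration_s = 10, heart_rate_bpm = 60, fs = 360,
                         seed = 1L, ...) {
  synthesis_config(fs = fs, duration_s = duration_s,
                   heart_rate_bpm = heart_rate_bpm,
                   powerline_amp = 0, baseline_amp = 0, white_sigma = 0,
                   seed = seed, ...)
}

noisy_config <- function(duration_s = 10, heart_rate_bpm = 60, fs = 360,
                         seed = 1L, ...) {
  synthesis_config(fs = fs, duration_s = duration_s,
                   heart_rate_bpm = heart_rate_bpm, seed = seed, ...)
}

# sensitivity and positive predictivity of detected vs true peaks at a
# +/- tol_ms matching window
match_peaks <- function(detected, truth, fs, tol_ms = 40) {
  tol <- round(tol_ms * fs / 1000)
  tp <- sum(vapply(truth, function(a) any(abs(detected - a) <= tol),
                   logical(1)))
  fp <- sum(vapply(detected, function(p) !any(abs(truth - p) <= tol),
                   logical(1)))
  list(sensitivity = tp / length(truth),
       ppv = if (length(detected) == 0) NA_real_
             else (length(detected) - fp) / length(detected))
}

# two-Gaussian-cluster score data for classifier recovery tests
two_cluster_scores <- function(n = 400, d = 2, separation = 5, sigma = 1,
                               seed = 1L) {
  set.seed(seed)
  n1 <- n %/% 2
  n2 <- n - n1
  X <- rbind(matrix(rnorm(n1 * d, mean = 0, sd = sigma), n1, d),
             matrix(rnorm(n2 * d, mean = separation * sigma, sd = sigma),
                    n2, d))
  y <- factor(rep(c("normal", "abnormal"), c(n1, n2)),
              levels = c("normal", "abnormal"))
  perm <- sample(n)
  list(X = X[perm, , drop = FALSE], y = y[perm])
}
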