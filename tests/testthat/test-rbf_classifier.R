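test_that("Gaussian kernel values at characteristic distances", {
  expect_equal(gaussian_kernel(c(1, 2), c(1, 2), 1), 1)
  expect_equal(gaussian_kernel(0, 1, 1), exp(-1 / 2), tolerance = 1e-12)
  expect_equal(gaussian_kernel(c(0, 0), c(1, 1), 1), exp(-1),
               tolerance = 1e-12)
  expect_error(gaussian_kernel(0, 1, 0), "sigma")
  expect_error(gaussian_kernel(1:2, 1:3, 1), "mismatch")
})

test_that("center grid spans the per-dimension min-max range", {
  X <- matrix(c(0, 3, 10, 7), ncol = 1)
  expect_equal(rbf_init_centers(X, 3)[, 1], c(0, 5, 10))
  expect_equal(rbf_init_centers(X, 1)[, 1], 5)
  Xc <- matrix(2, 5, 3)
  expect_true(all(rbf_init_centers(Xc, 4) == 2))
  X2 <- cbind(c(0, 10), c(-2, 2))
  ctr <- rbf_init_centers(X2, 5)
  expect_equal(dim(ctr), c(5, 2))
  expect_equal(ctr[, 1], seq(0, 10, by = 2.5))
  expect_equal(ctr[, 2], seq(-2, 2, by = 1))
})

test_that("widths are mean sample-to-center distances with a positive floor", {
  X <- matrix(c(0, 2), ncol = 1)
  expect_equal(rbf_init_widths(X, matrix(1)), 1)
  # all samples at the center: floored, never zero
  w0 <- rbf_init_widths(matrix(1, 5, 2), matrix(1, 1, 2))
  expect_gt(w0, 0)
  set.seed(14)
  Xr <- matrix(rnorm(30), 10, 3)
  ctr <- rbf_init_centers(Xr, 4)
  w <- rbf_init_widths(Xr, ctr)
  naive <- vapply(seq_len(4), function(j) {
    mean(vapply(seq_len(10),
                function(i) euclidean_distance(Xr[i, ], ctr[j, ]),
                numeric(1)))
  }, numeric(1))
  expect_equal(w, naive, tolerance = 1e-10)
})

test_that("forward pass equals the naive kernel summation", {
  set.seed(5)
  H <- 4
  model <- structure(list(centers = matrix(rnorm(H * 2), H, 2),
                          widths = runif(H, 0.5, 2),
                          weights = rnorm(H), bias = rnorm(1),
                          decision_threshold = 0.5,
                          rms_trace = NA_real_, solver = "least_squares"),
                     class = "rbf_model")
  X <- matrix(rnorm(12), 6, 2)
  naive <- vapply(seq_len(6), function(i) {
    model$bias + sum(vapply(seq_len(H), function(j) {
      model$weights[j] *
        gaussian_kernel(X[i, ], model$centers[j, ], model$widths[j])
    }, numeric(1)))
  }, numeric(1))
  expect_equal(rbf_forward(model, X), naive, tolerance = 1e-12)
  # zero weights and bias -> zero everywhere
  model$weights[] <- 0; model$bias <- 0
  expect_equal(rbf_forward(model, X), numeric(6))
})

test_that("RMS error: perfect fit, unit residuals, homogeneity", {
  expect_equal(rms_error(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(rms_error(c(0, 0), c(1, 1)), 1)
  set.seed(3)
  o <- rnorm(10); t <- rnorm(10)
  expect_equal(rms_error(3 * o, 3 * t), 3 * rms_error(o, t),
               tolerance = 1e-12)
  expect_error(rms_error(1:3, 1:4), "mismatch")
})

test_that("separable 1-D clusters train to perfect accuracy with H = 2", {
  set.seed(1)
  X <- matrix(c(rnorm(20, 0, 0.3), rnorm(20, 10, 0.3)), ncol = 1)
  y <- rep(c("abnormal", "normal"), each = 20)
  model <- rbf_train(X, y, H = 2)
  expect_equal(as.character(rbf_predict(model, X)), y)
  # threshold semantics: score exactly at threshold classifies normal
  expect_equal(as.character(rbf_predict(model, X,
                                        threshold = min(rbf_forward(model, X)))),
               rep("normal", 40))
  # raising the threshold never converts abnormal -> normal
  p_low <- rbf_predict(model, X, threshold = 0.3)
  p_high <- rbf_predict(model, X, threshold = 0.7)
  expect_false(any(p_low == "abnormal" & p_high == "normal"))
})

test_that("training guards: single class, H too large, bad labels", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(rbf_train(X, rep("normal", 10), H = 2), "both classes")
  expect_error(rbf_train(X, rep(c("normal", "abnormal"), 5), H = 11),
               "exceeds")
  expect_error(rbf_train(X, rep(c("yes", "no"), 5), H = 2), "normal")
})

test_that("least-squares weights reproduce the normal-equation oracle", {
  for (s in 1:5) {
    set.seed(s)
    N <- sample(20:50, 1)
    H <- sample(2:8, 1)
    X <- matrix(rnorm(2 * N), N, 2)
    y <- as.numeric(X[, 1] + 0.3 * rnorm(N) > 0)
    if (length(unique(y)) < 2) next
    model <- rbf_train(X, y, H = H)
    phi <- cbind(1, ecgflow:::.rbf_phi(X, model$centers, model$widths))
    beta <- solve(crossprod(phi), crossprod(phi, y))
    got <- c(model$bias, model$weights)
    expect_lt(max(abs(got - beta)) / max(1, max(abs(beta))), 1e-6)
  }
})

test_that("gradient solver honors the RMS jump-out rule", {
  set.seed(2)
  X <- matrix(c(rnorm(15, 0), rnorm(15, 8)), ncol = 1)
  y <- rep(c(0, 1), each = 15)
  m_inf <- rbf_train(X, y, H = 2, solver = "gradient", epsilon = Inf,
                     max_epochs = 100)
  expect_equal(length(m_inf$rms_trace), 1)   # stops after the first epoch
  m_ls <- rbf_train(X, y, H = 2)
  m_gd <- rbf_train(X, y, H = 2, solver = "gradient", epsilon = 1e-6,
                    max_epochs = 200)
  # least squares is optimal for the linear output layer
  expect_lte(m_ls$rms_trace[1], min(m_gd$rms_trace) + 1e-9)
  # gradient RMS decreases overall
  expect_lt(tail(m_gd$rms_trace, 1), m_gd$rms_trace[1])
})

test_that("held-out accuracy exceeds 99% on well-separated score clusters", {
  for (H in c(2, 5, 10)) {
    dat <- two_cluster_scores(n = 400, d = 2, separation = 5, seed = 100 + H)
    tr <- seq_len(300)
    te <- 301:400
    model <- rbf_train(dat$X[tr, ], dat$y[tr], H = H)
    pred <- rbf_predict(model, dat$X[te, ])
    acc <- mean(pred == dat$y[te])
    expect_gte(acc, 0.99)
  }
})

test_that("forward is continuous: small perturbations move scores little", {
  set.seed(4)
  dat <- two_cluster_scores(n = 60, d = 2, separation = 4, seed = 9)
  model <- rbf_train(dat$X, dat$y, H = 5)
  delta <- 1e-4
  lip <- sum(abs(model$weights)) / (min(model$widths) * exp(0.5))
  for (i in 1:10) {
    x <- dat$X[i, ]
    shift <- rnorm(2)
    shift <- shift / sqrt(sum(shift^2)) * delta
    d_score <- abs(rbf_forward(model, x + shift) - rbf_forward(model, x))
    expect_lte(d_score, lip * delta * (1 + 1e-6))
  }
})

test_that("RBF models serialize losslessly to JSON", {
  dat <- two_cluster_scores(n = 40, separation = 4, seed = 3)
  model <- rbf_train(dat$X, dat$y, H = 3)
  p <- withr::local_tempfile(fileext = ".json")
  write_rbf_model(model, p)
  back <- read_rbf_model(p)
  expect_equal(rbf_forward(back, dat$X), rbf_forward(model, dat$X),
               tolerance = 1e-12)
  expect_equal(back$decision_threshold, model$decision_threshold)
})
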