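# Reservoir construction, state recursion, readout training, smoothing

make_hand_model <- function(W_in, W, alpha, W_out = NULL) {
  structure(list(
    W_in = W_in, W = Matrix::Matrix(W, sparse = TRUE), W_out = W_out,
    state = numeric(nrow(W)),
    config = reservoir_config(n_internal = nrow(W), leaking_rate = max(alpha, 1e-9)),
    n_features = ncol(W_in) - 1L, feature_names = NULL
  ), class = "esn_model")
}

test_that("reservoir construction hits the target spectral radius and sparsity", {
  cfg <- reservoir_config(n_internal = 200, connectivity = 0.1,
                          spectral_radius = 1.3, seed = 7)
  m <- init_reservoir(cfg, n_features = 5)
  sr <- max(Mod(eigen(as.matrix(m$W), only.values = TRUE)$values))
  expect_equal(sr, 1.3, tolerance = 1e-6)
  # nonzero fraction within 3 binomial sigma of c
  frac <- Matrix::nnzero(m$W) / 200^2
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / 200^2))
  # W_in has a bias column and the input-scaling bound
  expect_equal(dim(m$W_in), c(200, 6))
  expect_true(all(abs(m$W_in) <= cfg$input_scaling))
  # determinism
  m2 <- init_reservoir(cfg, n_features = 5)
  expect_identical(as.matrix(m$W), as.matrix(m2$W))
  expect_identical(m$W_in, m2$W_in)
})

test_that("an unrescalable draw is resampled with a warning", {
  cfg <- reservoir_config(n_internal = 2, connectivity = 0.01, seed = 1)
  # the resampling loop may warn many times before a rescalable draw appears
  suppressWarnings(expect_warning(m <- init_reservoir(cfg, n_features = 1), "resampling"))
  sr <- max(Mod(eigen(as.matrix(m$W), only.values = TRUE)$values))
  expect_equal(sr, cfg$spectral_radius, tolerance = 1e-6)
})

test_that("the leaky update follows its closed form at the alpha boundaries", {
  W_in <- matrix(c(1, 0, 0, 0), 2, 2) # feature weight column + zero bias column
  W <- matrix(c(0, 0.5, 0.5, 0), 2, 2, byrow = TRUE)
  m0 <- make_hand_model(W_in, W, alpha = 0)
  m0$config$leaking_rate <- 0 # boundary value, below the config's domain
  expect_equal(update_state(m0, c(0.2, -0.3), u = 1), c(0.2, -0.3))
  m1 <- make_hand_model(W_in, W, alpha = 1)
  x_prev <- c(0.2, -0.3)
  expect_equal(update_state(m1, x_prev, u = 1),
               tanh(as.numeric(W_in %*% c(1, 1)) + as.numeric(W %*% x_prev)))
  # hand-computed half-leak step
  mh <- make_hand_model(W_in, W, alpha = 0.5)
  expect_equal(update_state(mh, c(0, 0), u = 1), c(0.5 * tanh(1), 0),
               tolerance = 1e-12)
  expect_error(update_state(mh, c(0, NA), u = 1), "non-finite")
})

test_that("run_sequence equals an independent step-by-step recursion", {
  cfg <- reservoir_config(n_internal = 20, seed = 3)
  m <- init_reservoir(cfg, n_features = 4)
  U <- withr::with_seed(5, matrix(rnorm(30 * 4), 30, 4))
  st <- run_sequence(m, U)
  # loop oracle written from the recursion's definition
  a <- cfg$leaking_rate
  Wd <- as.matrix(m$W)
  x <- numeric(20)
  for (t in 1:30) {
    x <- (1 - a) * x + a * tanh(as.numeric(m$W_in %*% c(U[t, ], 1)) + as.numeric(Wd %*% x))
    expect_equal(st[t, ], x, tolerance = 1e-12)
  }
  expect_equal(attr(st, "final_state"), x, tolerance = 1e-12)
  # base cases
  expect_equal(run_sequence(m, U[1, , drop = FALSE])[1, ],
               update_state(m, numeric(20), U[1, ]))
  empty <- run_sequence(m, U[0, , drop = FALSE], x0 = rep(0.3, 20))
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "final_state"), rep(0.3, 20))
  # states bounded in (-1, 1) from a zero start
  expect_true(all(abs(st) < 1))
})

test_that("the echo state property holds empirically below unit spectral radius", {
  for (s in 1:5) {
    cfg <- reservoir_config(n_internal = 50, leaking_rate = 0.5,
                            spectral_radius = 0.9, seed = s)
    m <- init_reservoir(cfg, n_features = 3)
    U <- withr::with_seed(100 + s, matrix(rnorm(500 * 3), 500, 3))
    x0b <- withr::with_seed(200 + s, runif(50, -1, 1))
    sa <- run_sequence(m, U, x0 = numeric(50))
    sb <- run_sequence(m, U, x0 = x0b)
    expect_lt(sqrt(sum((sa[500, ] - sb[500, ])^2)), 1e-3)
  }
})

test_that("ridge readout training recovers realizable targets and matches least squares", {
  withr::with_seed(11, {
    states <- matrix(rnorm(40 * 6), 40, 6)
    inputs <- matrix(rnorm(40 * 3), 40, 3)
    w_true <- rnorm(3 + 1 + 6)
    y <- as.numeric(cbind(inputs, 1, states) %*% w_true)
  })
  w <- train_readout(states, inputs, y, training_config(beta = 1e-8))
  yhat <- as.numeric(cbind(inputs, 1, states) %*% w)
  expect_lt(sqrt(mean((yhat - y)^2)), 1e-6)

  # beta -> infinity drives the readout to zero
  w_inf <- train_readout(states, inputs, y / max(abs(y)), training_config(beta = 1e12))
  expect_lt(sqrt(sum(w_inf^2)), 1e-6)

  # full-rank 20 x 5 design at beta = 1e-12 matches exact least squares
  withr::with_seed(12, {
    X <- matrix(rnorm(20 * 4), 20, 4) # + bias column -> 5 design columns
    yy <- rnorm(20)
  })
  w_ridge <- train_readout(matrix(0, 20, 0), X, yy, training_config(beta = 1e-12))
  w_ls <- unname(coef(lm(yy ~ X))) # oracle: QR least squares
  expect_equal(w_ridge, c(w_ls[-1], w_ls[1]), tolerance = 1e-6)

  expect_error(train_readout(states, inputs, y, training_config(washout = 40)),
               "washout")
})

test_that("prediction composes run_sequence with the readout and is deterministic", {
  cfg <- reservoir_config(n_internal = 15, seed = 9)
  m <- init_reservoir(cfg, n_features = 4)
  U <- withr::with_seed(13, matrix(rnorm(25 * 4), 25, 4))
  m$W_out <- rep(0, 4 + 1 + 15)
  expect_equal(predict_readout(m, U), rep(0, 25))
  m$W_out <- withr::with_seed(14, rnorm(4 + 1 + 15))
  y <- predict_readout(m, U)
  st <- run_sequence(m, U)
  oracle <- vapply(1:25, function(t) sum(c(U[t, ], 1, st[t, ]) * m$W_out), numeric(1))
  expect_equal(y, oracle, tolerance = 1e-12)
  expect_identical(y, predict_readout(m, U))
  m$W_out <- NULL
  expect_error(predict_readout(m, U), "no trained readout")
})

test_that("classification thresholds at zero with rest as tie-break", {
  expect_identical(classify_readout(c(0.3, -0.2, 1.5)), c(1L, -1L, 1L))
  expect_identical(classify_readout(0), -1L)
  y <- withr::with_seed(15, rnorm(500))
  expect_identical(classify_readout(y), ifelse(sign(y) > 0, 1L, -1L))
})

test_that("causal smoothing equals the brute-force windowed mean", {
  expect_identical(smooth_readout(c(3, 1, 4), 1), c(3, 1, 4))
  expect_equal(smooth_readout(c(1, -1, 1, -1), 2), c(1, 0, 0, 0))
  y <- withr::with_seed(16, rnorm(200))
  for (n in 1:12) expect_equal(smooth_readout(y, n), brute_smooth(y, n), tolerance = 1e-12)
  expect_equal(smooth_readout(numeric(0), 3), numeric(0))
  # idempotent on constants, variance-reducing otherwise
  expect_equal(smooth_readout(rep(2.5, 40), 6), rep(2.5, 40))
  for (n in 2:6) expect_lt(var(smooth_readout(y, n)), var(y))
  expect_error(smooth_readout(y, 0), "positive integer")
})

test_that("training fits only the readout: W_in and W are bitwise unchanged", {
  f <- cluster_features(n_segments = 6, seg_len = 15)
  cfg <- reservoir_config(n_internal = 30, seed = 21)
  before <- init_reservoir(cfg, n_features = 10)
  fit <- fit_esn(f, cfg)
  expect_identical(fit$W_in, before$W_in)
  expect_identical(as.matrix(fit$W), as.matrix(before$W))
})

test_that("the ESN separates Gaussian clusters and not label-shuffled ones", {
  train <- cluster_features(n_segments = 12, seg_len = 30, seed = 31)
  test <- cluster_features(n_segments = 8, seg_len = 30, seed = 32)
  cfg <- reservoir_config(n_internal = 100, leaking_rate = 0.3,
                          spectral_radius = 0.9, seed = 33)
  fit <- fit_esn(train, cfg)
  pred <- predict(fit, test)
  expect_gte(accuracy(pred$.pred, pred$label), 0.9)

  shuffled <- train
  shuffled$label <- withr::with_seed(34, sample(shuffled$label))
  fit0 <- fit_esn(shuffled, cfg)
  pred0 <- predict(fit0, test)
  acc0 <- accuracy(pred0$.pred, pred0$label)
  n <- nrow(test)
  expect_lt(abs(acc0 - 0.5), 1.96 * sqrt(0.25 / n) + 0.05)
})

test_that("tidy and glance expose the readout and the hyperparameters", {
  f <- cluster_features(n_segments = 4, seg_len = 10)
  fit <- suppressWarnings(fit_esn(f, reservoir_config(n_internal = 10, seed = 2)))
  td <- tidy(fit)
  expect_equal(nrow(td), 10 + 1 + 10)
  expect_setequal(unique(td$component), c("input", "bias", "reservoir"))
  g <- glance(fit)
  expect_equal(g$n_internal, 10)
  expect_equal(g$n_train, 40)
})
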