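test_that("analytic gradients match finite differences through every layer", {
  arch <- toy_architecture()
  e <- scalonet:::engine_layers(arch)
  set.seed(4)
  N <- 3
  X <- array(rnorm(prod(arch$input_shape) * N), c(arch$input_shape, N))
  y <- c(0, 1, 1)
  w <- scalonet:::init_weights(arch, 9)
  # non-zero biases keep the probe away from relu kinks at exactly zero
  set.seed(99)
  for (l in seq_along(w)) {
    if (!is.null(w[[l]])) w[[l]]$b <- stats::rnorm(length(w[[l]]$b), 0, 0.3)
  }
  g <- scalonet:::dcnn_grad_cpp(X, y, e$kind, e$kk, e$nout, e$act, e$rate, w)
  lossfn <- function(w) {
    scalonet:::dcnn_grad_cpp(X, y, e$kind, e$kk, e$nout, e$act, e$rate, w)$loss
  }
  eps <- 1e-6
  set.seed(123)
  for (l in seq_along(w)) {
    if (is.null(w[[l]])) next
    probes <- sample(length(w[[l]]$W), min(8, length(w[[l]]$W)))
    for (idx in c(probes)) {
      wp <- w; wp[[l]]$W[idx] <- wp[[l]]$W[idx] + eps
      wm <- w; wm[[l]]$W[idx] <- wm[[l]]$W[idx] - eps
      num <- (lossfn(wp) - lossfn(wm)) / (2 * eps)
      expect_equal(g$grads[[l]]$W[idx], num, tolerance = 1e-5)
    }
    for (idx in seq_along(w[[l]]$b)) {
      wp <- w; wp[[l]]$b[idx] <- wp[[l]]$b[idx] + eps
      wm <- w; wm[[l]]$b[idx] <- wm[[l]]$b[idx] - eps
      num <- (lossfn(wp) - lossfn(wm)) / (2 * eps)
      expect_equal(g$grads[[l]]$b[idx], num, tolerance = 1e-5)
    }
  }
})

test_that("forward pass yields probabilities and is deterministic at inference", {
  arch <- toy_architecture()
  m <- build_model(arch, train_config(seed = 5))
  set.seed(8)
  X <- array(runif(prod(arch$input_shape) * 2), c(arch$input_shape, 2))
  p <- predict_proba(m, X)
  expect_length(p, 2)
  expect_true(all(p >= 0 & p <= 1))
  # dropout is inactive outside training: bit-identical repeated passes
  expect_identical(p, predict_proba(m, X))
})

test_that("training histories, reproducibility and loss descent behave", {
  arch <- architecture_spec(c(24, 32, 3), list(
    layer_rescale_resize(c(12, 16)), layer_conv2d(3, 2), layer_maxpool(2),
    layer_flatten(), layer_dropout(0.2), layer_dense(8, "relu"),
    layer_dense(1, "sigmoid")))
  set.seed(2)
  N <- 12
  X <- array(runif(24 * 32 * 3 * N, 0, 0.5), c(24, 32, 3, N))
  y <- rep(c(0, 1), each = N / 2)
  X[1:10, , , y == 1] <- X[1:10, , , y == 1] + 0.5

  cfg1 <- train_config(epochs = 1, batch_size = 4, learning_rate = 2e-3, seed = 3)
  m1 <- train_model(build_model(arch, cfg1), X, y)
  expect_equal(nrow(m1$history), 1)
  expect_named(m1$history, c("epoch", "loss", "accuracy", "val_loss", "val_accuracy"))

  cfg <- train_config(epochs = 20, batch_size = 4, learning_rate = 2e-3, seed = 3)
  m <- train_model(build_model(arch, cfg), X, y, X, y)
  expect_lt(m$history$loss[20], m$history$loss[1])
  # seeded training is exactly reproducible
  m2 <- train_model(build_model(arch, cfg), X, y, X, y)
  expect_identical(m$weights, m2$weights)
  expect_identical(m$history, m2$history)

  expect_error(train_model(build_model(arch, cfg), X, rep(2, N)), "binary|epilepsy")
  expect_error(train_model(build_model(arch, cfg), X, character(0)), "empty|length|mismatch")
})

test_that("decision thresholding follows the boundary convention and is monotone", {
  expect_identical(apply_threshold(0.5, 0.5), 1L)   # boundary counts as epilepsy
  expect_identical(apply_threshold(c(0.1, 0.9), 0), c(1L, 1L))
  probs <- seq(0, 1, by = 0.05)
  counts <- vapply(seq(0, 1, by = 0.1), function(th) sum(apply_threshold(probs, th)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0)) # raising threshold never adds positives
})

test_that("model checkpoints survive a save/load round-trip", {
  m <- build_model(toy_architecture(), train_config(seed = 1))
  p <- tempfile(fileext = ".rds")
  save_model(m, p)
  m2 <- load_model(p)
  expect_identical(m2$weights, m$weights)
  set.seed(31)
  X <- array(runif(prod(m$arch$input_shape)), c(m$arch$input_shape, 1))
  expect_identical(predict_proba(m, X), predict_proba(m2, X))
})
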