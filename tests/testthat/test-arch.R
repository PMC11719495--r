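table1_shapes <- list(
  c(150L, 210L, 3L), c(148L, 208L, 4L), c(144L, 204L, 4L), c(142L, 202L, 8L),
  c(71L, 101L, 8L), c(67L, 97L, 8L), c(33L, 48L, 8L), 12672L, 12672L, 512L, 1L)

test_that("shape propagation reproduces every published layer shape", {
  arch <- default_architecture()
  expect_identical(propagate_shapes(arch), table1_shapes)
  # single-layer checks straight from the rules
  expect_identical(shape_after_layer(layer_conv2d(3, 4), c(150, 210, 3)),
                   c(148, 208, 4))
  expect_identical(shape_after_layer(layer_maxpool(2), c(142, 202, 8)),
                   c(71, 101, 8))
  expect_identical(shape_after_layer(layer_maxpool(2), c(67, 97, 8)),
                   c(33, 48, 8)) # floor division
})

test_that("shape propagation folds correctly for the 50x70 input", {
  shapes <- propagate_shapes(default_architecture(c(50, 70)))
  # 50x70 -> 48x68 -> 44x64 -> 42x62 -> 21x31 -> 17x27 -> 8x13; 8*13*8 = 832
  expect_identical(shapes[[7]], c(8L, 13L, 8L))
  expect_identical(shapes[[8]], 832L)
})

test_that("oversized kernels are rejected", {
  expect_error(shape_after_layer(layer_conv2d(5, 2), c(3, 3, 1)), "kernel")
  expect_error(architecture_spec(c(4, 4, 3), list(
    layer_conv2d(5, 2), layer_flatten(), layer_dense(1, "sigmoid"))), "kernel")
})

test_that("parameter counting follows the convolution arithmetic", {
  # depthwise 5x5 over 4 channels: 25*4 + 4
  dw <- architecture_spec(c(10, 10, 4), list(
    layer_depthwise(5), layer_flatten(), layer_dense(1, "sigmoid")))
  d1 <- propagate_shapes(dw)[[2]]
  expect_equal(count_parameters(dw) - (d1 * 1 + 1), 104)
  expect_equal(count_parameters(default_architecture()), 6489809)
  # dense 12672 -> 512 contributes 12672*512 + 512
  expect_equal(12672 * 512 + 512, 6488576)
})

test_that("engine-observed shapes and weights match the analytic propagation", {
  arch <- default_architecture()
  expect_identical(model_layer_shapes(arch), table1_shapes)
  m <- build_model(arch, train_config())
  expect_equal(model_parameter_count(m), count_parameters(arch))

  # property: random valid architectures agree between engine and fold
  set.seed(17)
  for (rep in 1:20) {
    h <- sample(18:40, 1)
    w <- sample(18:40, 1)
    layers <- list(layer_conv2d(sample(c(3, 5), 1), sample(2:6, 1)))
    if (runif(1) < 0.5) layers <- c(layers, list(layer_depthwise(3)))
    layers <- c(layers, list(layer_maxpool(2), layer_flatten()))
    if (runif(1) < 0.5) layers <- c(layers, list(layer_dropout(runif(1, 0.1, 0.8))))
    layers <- c(layers, list(layer_dense(sample(3:16, 1), "relu"),
                             layer_dense(1, "sigmoid")))
    arch_r <- architecture_spec(c(h, w, 3), layers)
    expect_identical(model_layer_shapes(arch_r),
                     lapply(propagate_shapes(arch_r), as.integer))
    expect_equal(model_parameter_count(build_model(arch_r, train_config())),
                 count_parameters(arch_r))
  }
})

test_that("architecture validation enforces the binary sigmoid head", {
  expect_error(architecture_spec(c(10, 10, 3), list(
    layer_flatten(), layer_dense(2, "sigmoid"))), "dense\\(1, sigmoid\\)")
  expect_error(architecture_spec(c(10, 10, 3), list(
    layer_flatten(), layer_dense(1, "relu"))), "dense\\(1, sigmoid\\)")
  expect_error(layer_conv2d(4, 2), "odd")
  expect_error(layer_dropout(1), "rate")
})
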