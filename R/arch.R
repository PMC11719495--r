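#' Layer constructors for the depthwise CNN architecture
#'
#' Declarative layer specs drive both analytic shape/parameter propagation
#' ([propagate_shapes()], [count_parameters()]) and the compiled engine
#' behind [build_model()]. Convolutions use valid padding and stride 1;
#' pooling uses stride 2 with floor division -- the only choices consistent
#' with the published output shapes.
#'
#' @param target `(height, width)` the resize layer maps any input to;
#'   pixel values are simultaneously scaled to `[0, 1]`
#' @param kernel odd kernel size `k` (the filter is `k x k`)
#' @param filters number of output channels (standard convolution)
#' @param units number of dense units
#' @param activation `"relu"`, `"sigmoid"`, or `"none"`
#' @param pool pooling window (and stride)
#' @param rate dropout fraction in `[0, 1)`
#' @return an object of class `layer_spec`
#' @name layers
NULL

#' @noRd
new_layer <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "layer_spec")
}

#' @rdname layers
#' @export
layer_rescale_resize <- function(target) {
  stop_if(length(target) != 2 || any(target < 1), "target must be (height, width)")
  new_layer("rescale_resize", target = as.integer(target))
}

#' @noRd
check_kernel <- function(kernel) {
  stop_if(!is_count(kernel) || kernel %% 2 == 0, "kernel must be odd and >= 1")
  as.integer(kernel)
}

#' @rdname layers
#' @export
layer_conv2d <- function(kernel, filters, activation = "relu") {
  stop_if(!is_count(filters), "filters must be a positive integer")
  new_layer("conv2d", kernel = check_kernel(kernel), filters = as.integer(filters),
            activation = match.arg(activation, c("relu", "sigmoid", "none")))
}

#' @rdname layers
#' @export
layer_depthwise <- function(kernel, activation = "relu") {
  new_layer("depthwise_conv2d", kernel = check_kernel(kernel),
            activation = match.arg(activation, c("relu", "sigmoid", "none")))
}

#' @rdname layers
#' @export
layer_maxpool <- function(pool = 2) {
  stop_if(!is_count(pool), "pool must be a positive integer")
  new_layer("maxpool2d", pool = as.integer(pool))
}

#' @rdname layers
#' @export
layer_flatten <- function() new_layer("flatten")

#' @rdname layers
#' @export
layer_dropout <- function(rate) {
  stop_if(!is.numeric(rate) || rate < 0 || rate >= 1, "rate must be in [0, 1)")
  new_layer("dropout", rate = rate)
}

#' @rdname layers
#' @export
layer_dense <- function(units, activation = "none") {
  stop_if(!is_count(units), "units must be a positive integer")
  new_layer("dense", units = as.integer(units),
            activation = match.arg(activation, c("relu", "sigmoid", "none")))
}

#' Architecture specification
#'
#' @param input_shape `(H, W, C)` of raw input images (default the 500x700
#'   RGB composite)
#' @param layers ordered list of [layers] specs; the last layer must be
#'   `layer_dense(1, "sigmoid")` for the binary task
#' @return an object of class `architecture_spec`
#' @export
architecture_spec <- function(input_shape = c(500, 700, 3), layers) {
  stop_if(length(input_shape) != 3 || any(input_shape < 1), "input_shape must be (H, W, C)")
  stop_if(!is.list(layers) || length(layers) == 0 ||
            !all(vapply(layers, inherits, logical(1), "layer_spec")),
          "layers must be a non-empty list of layer specs")
  last <- layers[[length(layers)]]
  stop_if(last$kind != "dense" || last$units != 1 || last$activation != "sigmoid",
          "last layer must be dense(1, sigmoid) for the binary task")
  arch <- structure(list(input_shape = as.integer(input_shape), layers = layers),
                    class = "architecture_spec")
  propagate_shapes(arch) # validates layer compatibility
  arch
}

#' The published depthwise-CNN architecture
#'
#' Resize to `input_size` (default 150x210) with values in `[0, 1]`, then
#' conv 3x3x4 relu, depthwise 5x5 relu, conv 3x3x8 relu, maxpool 2x2,
#' depthwise 5x5 relu, maxpool 2x2, flatten, dropout 0.6, dense 512 relu,
#' dense 1 sigmoid. With the default input size the flatten width is
#' 12,672 and the trainable parameter count 6,489,809. The alternative
#' input sizes of the experiment grid (50x70, 100x140, 200x280) are
#' selected through `input_size`.
#'
#' @param input_size `(height, width)` target of the resize layer
#' @param input_shape raw image shape fed to the network
#' @param dropout_rate dropout fraction before the 512-unit dense layer
#' @return an [architecture_spec()]
#' @export
default_architecture <- function(input_size = c(150, 210),
                                 input_shape = c(500, 700, 3),
                                 dropout_rate = 0.6) {
  architecture_spec(input_shape = input_shape, layers = list(
    layer_rescale_resize(input_size),
    layer_conv2d(3, 4, "relu"),
    layer_depthwise(5, "relu"),
    layer_conv2d(3, 8, "relu"),
    layer_maxpool(2),
    layer_depthwise(5, "relu"),
    layer_maxpool(2),
    layer_flatten(),
    layer_dropout(dropout_rate),
    layer_dense(512, "relu"),
    layer_dense(1, "sigmoid")
  ))
}

#' Output shape of a single layer
#'
#' Valid padding, stride 1 for convolutions (`H' = H - k + 1`); depthwise
#' convolution preserves the channel count (multiplier 1); max pooling
#' halves spatial dimensions with floor division.
#'
#' @param layer a [layers] spec
#' @param in_shape `(H, W, C)` vector, or a scalar after flattening
#' @return the output shape (vector or scalar)
#' @export
shape_after_layer <- function(layer, in_shape) {
  spatial <- function() stop_if(length(in_shape) != 3, layer$kind, " needs an (H, W, C) input")
  switch(layer$kind,
    rescale_resize = {
      spatial()
      c(layer$target, in_shape[3])
    },
    conv2d = ,
    depthwise_conv2d = {
      spatial()
      k <- layer$kernel
      stop_if(in_shape[1] < k || in_shape[2] < k,
              sprintf("kernel %d x %d exceeds input %d x %d", k, k, in_shape[1], in_shape[2]))
      ch <- if (layer$kind == "conv2d") layer$filters else in_shape[3]
      c(in_shape[1] - k + 1, in_shape[2] - k + 1, ch)
    },
    maxpool2d = {
      spatial()
      stop_if(any(in_shape[1:2] < layer$pool), "pool window exceeds input")
      c(in_shape[1] %/% layer$pool, in_shape[2] %/% layer$pool, in_shape[3])
    },
    flatten = {
      spatial()
      prod(in_shape)
    },
    dropout = in_shape,
    dense = {
      stop_if(length(in_shape) != 1, "dense needs a flattened input")
      layer$units
    },
    stop("unknown layer kind: ", layer$kind)
  )
}

#' Propagate shapes through an architecture
#'
#' @param arch an [architecture_spec()]
#' @return list of per-layer output shapes (integer vectors / scalars),
#'   one entry per layer in order
#' @export
propagate_shapes <- function(arch) {
  shape <- arch$input_shape
  out <- vector("list", length(arch$layers))
  for (i in seq_along(arch$layers)) {
    shape <- shape_after_layer(arch$layers[[i]], shape)
    out[[i]] <- as.integer(shape)
  }
  out
}

#' Trainable parameter count of an architecture
#'
#' Standard convolution contributes `k^2 * C_in * C_out + C_out`,
#' depthwise convolution `k^2 * C + C`, a dense layer
#' `n_in * n_out + n_out`; resize, pooling, flatten and dropout carry no
#' parameters.
#'
#' @param arch an [architecture_spec()]
#' @return total trainable parameter count
#' @export
count_parameters <- function(arch) {
  shape <- arch$input_shape
  total <- 0
  for (layer in arch$layers) {
    total <- total + switch(layer$kind,
      conv2d = layer$kernel^2 * shape[3] * layer$filters + layer$filters,
      depthwise_conv2d = layer$kernel^2 * shape[3] + shape[3],
      dense = shape * layer$units + layer$units,
      0)
    shape <- shape_after_layer(layer, shape)
  }
  total
}

#' @export
print.architecture_spec <- function(x, ...) {
  shapes <- propagate_shapes(x)
  cat(sprintf("<architecture_spec> input (%s), %s parameters\n",
              paste(x$input_shape, collapse = ", "),
              format(count_parameters(x), big.mark = ",")))
  for (i in seq_along(x$layers)) {
    cat(sprintf("  %2d %-18s (%s)\n", i, x$layers[[i]]$kind,
                paste(shapes[[i]], collapse = ", ")))
  }
  invisible(x)
}
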