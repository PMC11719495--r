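#' Training configuration
#'
#' Defaults follow the published protocol: Adam with learning rate 0.0002,
#' batch size 128, 100 epochs, binary cross-entropy loss, sigmoid decision
#' threshold 0.5.
#'
#' @param optimizer `"adam"` or `"rmsprop"`
#' @param learning_rate positive step size
#' @param batch_size minibatch size, >= 1
#' @param epochs training epochs
#' @param seed integer seed for weight initialization, shuffling, dropout
#' @param threshold decision cutoff on the sigmoid output; a segment is
#'   called epileptic iff probability >= threshold
#' @return an object of class `train_config`
#' @export
train_config <- function(optimizer = c("adam", "rmsprop"), learning_rate = 2e-4,
                         batch_size = 128, epochs = 100, seed = 1L,
                         threshold = 0.5) {
  optimizer <- match.arg(optimizer)
  stop_if(!is.numeric(learning_rate) || learning_rate <= 0, "learning_rate must be > 0")
  stop_if(!is_count(batch_size), "batch_size must be >= 1")
  stop_if(!is_count(epochs), "epochs must be >= 1")
  stop_if(threshold < 0 || threshold > 1, "threshold must be in [0, 1]")
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 loss = "binary_crossentropy", seed = as.integer(seed),
                 threshold = threshold),
            class = "train_config")
}

# engine encoding of an architecture: the leading rescale_resize layer is
# realized as input preprocessing (see prepare_images); everything after it
# is executed by the compiled engine.
#' @noRd
engine_layers <- function(arch) {
  layers <- arch$layers
  if (layers[[1]]$kind == "rescale_resize") {
    target <- layers[[1]]$target
    layers <- layers[-1]
  } else {
    target <- arch$input_shape[1:2]
  }
  stop_if(any(vapply(layers, function(l) l$kind == "rescale_resize", logical(1))),
          "rescale_resize is only supported as the first layer")
  kind_code <- c(conv2d = 1L, depthwise_conv2d = 2L, maxpool2d = 3L,
                 flatten = 4L, dropout = 5L, dense = 6L)
  act_code <- c(none = 0L, relu = 1L, sigmoid = 2L)
  list(
    target = target,
    kind = vapply(layers, function(l) kind_code[[l$kind]], integer(1)),
    kk = vapply(layers, function(l) as.integer(l$kernel %||% l$pool %||% 0L), integer(1)),
    nout = vapply(layers, function(l) as.integer(l$filters %||% l$units %||% 0L), integer(1)),
    act = vapply(layers, function(l) act_code[[l$activation %||% "none"]], integer(1)),
    rate = vapply(layers, function(l) as.numeric(l$rate %||% 0), numeric(1))
  )
}

#' @noRd
engine_probe <- function(arch) {
  el <- engine_layers(arch)
  dcnn_probe_cpp(el$target[1], el$target[2], arch$input_shape[3],
                 el$kind, el$kk, el$nout, el$act, el$rate)
}

# Glorot-uniform initialization over the weight dimensions the engine
# itself requires (dcnn_probe_cpp), seeded through R's RNG.
#' @noRd
init_weights <- function(arch, seed) {
  el <- engine_layers(arch)
  wdims <- engine_probe(arch)$weight_dims
  with_seed(seed, lapply(seq_along(wdims), function(l) {
    wd <- wdims[[l]]
    if (is.null(wd)) return(NULL)
    kind <- el$kind[l]
    k <- el$kk[l]
    fan <- if (kind == 1L) { # conv: fan_in = k^2*Cin, fan_out = k^2*Cout
      c(wd[1], k^2 * wd[2])
    } else if (kind == 2L) { # depthwise, multiplier 1
      c(k^2, k^2)
    } else { # dense
      c(wd[1], wd[2])
    }
    limit <- sqrt(6 / sum(fan))
    list(W = matrix(stats::runif(wd[1] * wd[2], -limit, limit), wd[1], wd[2]),
         b = rep(0, wd[3]))
  }))
}

#' Build a trainable depthwise-CNN model
#'
#' Instantiates the architecture with Glorot-uniform weights (seeded from
#' `config$seed`). The model's forward pass realizes the architecture
#' exactly: the leading resize layer maps any input image to the target
#' size with values scaled to `[0, 1]`, convolutions use valid padding and
#' stride 1, pools stride 2, and dropout is active only during training.
#'
#' @param arch an [architecture_spec()]
#' @param config a [train_config()]
#' @return an object of class `dcnn_model`
#' @export
build_model <- function(arch = default_architecture(), config = train_config()) {
  stop_if(!inherits(arch, "architecture_spec"), "arch must be an architecture_spec")
  stop_if(!inherits(config, "train_config"), "config must be a train_config")
  structure(list(arch = arch, config = config,
                 weights = init_weights(arch, config$seed),
                 fitted = FALSE, history = NULL),
            class = "dcnn_model")
}

#' Layer output shapes as reported by the compiled engine
#'
#' Runs the engine's real layer operations on a dummy input and returns the
#' observed per-layer output shapes (the resize layer's target shape
#' first). Serves as the execution-side counterpart of the analytic
#' [propagate_shapes()].
#'
#' @param model a [build_model()] result (or an [architecture_spec()])
#' @return list of integer shape vectors, one per layer
#' @export
model_layer_shapes <- function(model) {
  arch <- if (inherits(model, "dcnn_model")) model$arch else model
  shapes <- engine_probe(arch)$shapes
  if (arch$layers[[1]]$kind == "rescale_resize") {
    shapes <- c(list(as.integer(c(arch$layers[[1]]$target, arch$input_shape[3]))), shapes)
  }
  lapply(shapes, as.integer)
}

#' Trainable parameter count of an instantiated model
#'
#' Counts the elements of the weight tensors the engine actually
#' allocates, independently of the analytic [count_parameters()] formulas.
#'
#' @param model a `dcnn_model`
#' @return total number of trainable parameters
#' @export
model_parameter_count <- function(model) {
  sum(vapply(model$weights, function(w) {
    if (is.null(w)) 0 else length(w$W) + length(w$b)
  }, numeric(1)))
}

# raw images (H x W x 3 x N array or list of H x W x 3) -> engine input:
# resized to the architecture's target and scaled to [0, 1]
#' @noRd
prepare_images <- function(images, arch) {
  if (is.list(images)) {
    images <- simplify2array(images)
  }
  d <- dim(images)
  if (length(d) == 3) {
    dim(images) <- c(d, 1)
    d <- dim(images)
  }
  stop_if(length(d) != 4 || d[3] != 3, "images must be H x W x 3 x N")
  el <- engine_layers(arch)
  th <- el$target[1]
  tw <- el$target[2]
  scale <- if (max(images) > 1) 255 else 1
  out <- array(0, c(th, tw, 3, d[4]))
  for (n in seq_len(d[4])) {
    out[, , , n] <- resize_bilinear(images[, , , n] / scale, th, tw)
  }
  out
}

#' @noRd
to_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    stop_if(!all(labels %in% c("epilepsy", "normal")),
            "labels must be 'epilepsy' or 'normal'")
    as.numeric(labels == "epilepsy")
  } else {
    stop_if(!all(labels %in% c(0, 1)), "numeric labels must be binary 0/1")
    as.numeric(labels)
  }
}

#' Train the depthwise CNN
#'
#' Minimizes binary cross-entropy with the configured optimizer. Weight
#' initialization, epoch shuffling and dropout masks are all seeded, so a
#' rerun with the same inputs and seed reproduces the fit exactly.
#'
#' @param model a [build_model()] result
#' @param train_images raw images (`H x W x 3 x N` array or list), e.g.
#'   500x700 composites; resized internally by the model's first layer
#' @param train_labels binary labels (1/"epilepsy" = positive)
#' @param eval_images,eval_labels optional held-out set monitored per epoch
#' @param config a [train_config()]; defaults to the model's own
#' @return the fitted model, with `$history` a data.frame of per-epoch
#'   train/eval loss and accuracy
#' @export
train_model <- function(model, train_images, train_labels,
                        eval_images = NULL, eval_labels = NULL,
                        config = model$config) {
  stop_if(!inherits(model, "dcnn_model"), "model must be a dcnn_model")
  y <- to_binary_labels(train_labels)
  stop_if(length(y) == 0, "empty training set")
  x <- prepare_images(train_images, model$arch)
  stop_if(dim(x)[4] != length(y), "image/label count mismatch")
  has_val <- !is.null(eval_images)
  xv <- if (has_val) prepare_images(eval_images, model$arch) else array(0, c(1, 1, 3, 1))
  yv <- if (has_val) to_binary_labels(eval_labels) else numeric(0)
  el <- engine_layers(model$arch)
  fit <- dcnn_train_cpp(x, y, xv, yv, el$kind, el$kk, el$nout, el$act, el$rate,
                        model$weights, config$epochs, config$batch_size,
                        config$learning_rate,
                        if (config$optimizer == "adam") 1L else 2L,
                        config$seed, config$threshold)
  model$weights <- fit$weights
  h <- as.data.frame(fit$history)
  names(h) <- c("loss", "accuracy", "val_loss", "val_accuracy")
  h <- cbind(epoch = seq_len(nrow(h)), h)
  if (!has_val) h$val_loss <- h$val_accuracy <- NA_real_
  model$history <- h
  model$config <- config
  model$fitted <- TRUE
  model
}

#' Predicted epilepsy probabilities
#'
#' @param model a (fitted) `dcnn_model`
#' @param images raw images as in [train_model()]
#' @return numeric vector of sigmoid outputs in `[0, 1]`
#' @export
predict_proba <- function(model, images) {
  stop_if(!inherits(model, "dcnn_model"), "model must be a dcnn_model")
  x <- prepare_images(images, model$arch)
  el <- engine_layers(model$arch)
  as.numeric(dcnn_predict_cpp(x, el$kind, el$kk, el$nout, el$act, el$rate,
                              model$weights))
}

#' Threshold probabilities into binary labels
#'
#' A segment is labelled epileptic (1) iff its probability is greater than
#' or equal to `threshold`.
#'
#' @param probs numeric vector in `[0, 1]`
#' @param threshold decision cutoff
#' @return integer vector of 0/1 labels
#' @export
apply_threshold <- function(probs, threshold = 0.5) {
  as.integer(probs >= threshold)
}

#' @rdname predict_proba
#' @param threshold decision cutoff; defaults to the model's configured one
#' @export
predict_labels <- function(model, images, threshold = model$config$threshold) {
  apply_threshold(predict_proba(model, images), threshold)
}

#' Save / load a model checkpoint
#'
#' @param model a `dcnn_model`
#' @param path checkpoint file path
#' @return the path (save) or the model (load)
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stop_if(!inherits(model, "dcnn_model"), "not a dcnn_model checkpoint")
  model
}

#' Export a training history as tab-separated text
#'
#' @param history the `$history` data.frame of a fitted model
#' @param path output file
#' @export
write_history <- function(history, path) {
  utils::write.table(history, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.dcnn_model <- function(x, ...) {
  cat(sprintf("<dcnn_model> %s, %s parameters, %s\n",
              paste(x$arch$layers[[1]]$target %||% x$arch$input_shape[1:2],
                    collapse = "x"),
              format(model_parameter_count(x), big.mark = ","),
              if (x$fitted) sprintf("fitted (%d epochs)", nrow(x$history)) else "unfitted"))
  invisible(x)
}
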