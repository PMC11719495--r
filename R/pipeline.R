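#' Pipeline configuration
#'
#' Bundles all stage configurations plus the on-disk layout. One global
#' seed is expanded into independent per-stage seeds (simulation, split,
#' training) by [derive_seed()], so stages can be rerun independently
#' without disturbing each other's streams.
#'
#' @param out_dir root output directory; segments, per-channel images,
#'   composites, models and reports live in subdirectories
#' @param seed global seed
#' @param synthetic a [synthetic_config()]; its seed is overridden by the
#'   derived stage seed
#' @param cwt a [cwt_params()]
#' @param layout a [tile_layout()]
#' @param input_size network input `(height, width)`: one of the
#'   experiment grid sizes 50x70, 100x140, 150x210 (default), 200x280, or
#'   any other valid size
#' @param train a [train_config()] (seed overridden as above)
#' @param split a [split_spec()] (seed overridden as above)
#' @return an object of class `pipeline_config`
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            synthetic = synthetic_config(),
                            cwt = cwt_params(),
                            layout = tile_layout(),
                            input_size = c(150, 210),
                            train = train_config(),
                            split = split_spec()) {
  synthetic$seed <- derive_seed(seed, 101)
  split$seed <- derive_seed(seed, 102)
  train$seed <- derive_seed(seed, 103)
  paths <- list(data = file.path(out_dir, "segments"),
                images = file.path(out_dir, "images"),
                composites = file.path(out_dir, "composites"),
                models = file.path(out_dir, "models"),
                reports = file.path(out_dir, "reports"))
  structure(list(out_dir = out_dir, seed = as.integer(seed), paths = paths,
                 synthetic = synthetic, cwt = cwt, layout = layout,
                 input_size = as.integer(input_size), train = train, split = split),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys: `out_dir`, `seed`, `input_size` (e.g. `[100, 140]`),
#' `epochs`, `batch_size`, `optimizer`, `learning_rate`, `threshold`,
#' `n_subjects_per_class`, `segments_per_subject_range`, `fs`,
#' `train_fraction`, `split_mode`. Missing keys fall back to the package
#' defaults.
#'
#' @param path YAML file
#' @param out_dir overrides the file's `out_dir` when given
#' @return a [pipeline_config()]
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  stop_if(!requireNamespace("yaml", quietly = TRUE), "the 'yaml' package is required")
  y <- yaml::read_yaml(path)
  syn <- synthetic_config(
    n_subjects_per_class = y$n_subjects_per_class %||% 40,
    segments_per_subject_range = y$segments_per_subject_range %||% c(6, 10),
    fs = y$fs %||% 500)
  tr <- train_config(optimizer = y$optimizer %||% "adam",
                     learning_rate = y$learning_rate %||% 2e-4,
                     batch_size = y$batch_size %||% 128,
                     epochs = y$epochs %||% 100,
                     threshold = y$threshold %||% 0.5)
  sp <- split_spec(train_fraction = y$train_fraction %||% 0.75,
                   mode = y$split_mode %||% "segment")
  pipeline_config(out_dir %||% y$out_dir %||% ".", seed = y$seed %||% 1L,
                  synthetic = syn, input_size = y$input_size %||% c(150, 210),
                  train = tr, split = sp)
}

#' @noRd
manifest_path <- function(config) file.path(config$paths$data, "manifest.tsv")

#' @noRd
tile_paths <- function(config, subject_id, segment_id) {
  file.path(config$paths$images,
            sprintf("%s_%s_ch%02d.png", subject_id, segment_id,
                    seq_len(config$layout$n_tiles) - 1L))
}

#' @noRd
composite_path <- function(config, subject_id, segment_id) {
  file.path(config$paths$composites, sprintf("%s_%s.png", subject_id, segment_id))
}

#' Pipeline step 1: simulate and write the synthetic dataset
#'
#' @param config a [pipeline_config()]
#' @return the written dataset, invisibly
#' @export
cmd_simulate <- function(config) {
  ds <- generate_dataset(config$synthetic)
  ds <- write_dataset(ds, config$paths$data)
  write_manifest(ds$manifest, manifest_path(config))
  message(sprintf("simulate: %d segments -> %s", nrow(ds$manifest), config$paths$data))
  invisible(ds)
}

#' Pipeline step 2: render per-channel scalogram PNGs
#'
#' Writes 35 deterministic PNGs per segment, named
#' `<subject>_<segment>_ch<i>.png` with `i` the 0-based channel position.
#' Resumable: segments whose 35 images already exist are skipped; missing
#' segment files are reported together.
#'
#' @param config a [pipeline_config()]
#' @return number of newly written PNGs, invisibly
#' @export
cmd_scalogram <- function(config) {
  manifest <- read_manifest(manifest_path(config))
  dir.create(config$paths$images, recursive = TRUE, showWarnings = FALSE)
  missing <- manifest$path[!file.exists(manifest$path)]
  stop_if(length(missing) > 0, "missing segment files:\n  ",
          paste(missing, collapse = "\n  "))
  n_new <- 0
  for (r in seq_len(nrow(manifest))) {
    paths <- tile_paths(config, manifest$subject_id[r], manifest$segment_id[r])
    if (all(file.exists(paths))) next
    seg <- read_segment(manifest$path[r],
                        n_channels = config$synthetic$n_channels)
    tiles <- segment_scalograms(seg, config$cwt, config$layout$tile_size)
    for (i in seq_along(tiles)) write_image(tiles[[i]], paths[i])
    n_new <- n_new + length(tiles)
  }
  message(sprintf("scalogram: %d new PNGs in %s", n_new, config$paths$images))
  invisible(n_new)
}

#' Pipeline step 3: tile the 35 channel images into composites
#'
#' @param config a [pipeline_config()]
#' @return number of newly written composites, invisibly
#' @export
cmd_tile <- function(config) {
  manifest <- read_manifest(manifest_path(config))
  dir.create(config$paths$composites, recursive = TRUE, showWarnings = FALSE)
  n_new <- 0
  for (r in seq_len(nrow(manifest))) {
    out <- composite_path(config, manifest$subject_id[r], manifest$segment_id[r])
    if (file.exists(out)) next
    paths <- tile_paths(config, manifest$subject_id[r], manifest$segment_id[r])
    missing <- paths[!file.exists(paths)]
    stop_if(length(missing) > 0, "missing channel images:\n  ",
            paste(missing, collapse = "\n  "))
    tiles <- lapply(paths, read_image)
    write_image(compose(tiles, config$layout), out)
    n_new <- n_new + 1
  }
  message(sprintf("tile: %d new composites in %s", n_new, config$paths$composites))
  invisible(n_new)
}

# load composites for the given manifest rows, resized to the network
# input size, as an (h, w, 3, N) array in [0, 1]
#' @noRd
load_composites <- function(config, manifest) {
  th <- config$input_size[1]
  tw <- config$input_size[2]
  out <- array(0, c(th, tw, 3, nrow(manifest)))
  for (r in seq_len(nrow(manifest))) {
    p <- composite_path(config, manifest$subject_id[r], manifest$segment_id[r])
    stop_if(!file.exists(p), "missing composite: ", p)
    out[, , , r] <- resize_bilinear(png::readPNG(p)[, , 1:3], th, tw)
  }
  out
}

#' Pipeline step 4: train the model on the train split
#'
#' Splits the manifest with the configured [split_spec()], trains the
#' depthwise CNN on the training composites (monitoring the eval split),
#' and writes the checkpoint plus a per-epoch history table.
#'
#' @param config a [pipeline_config()]
#' @return the fitted model, invisibly
#' @export
cmd_train <- function(config) {
  manifest <- read_manifest(manifest_path(config))
  parts <- split_dataset(manifest, config$split)
  stop_if(nrow(parts$train) == 0 || nrow(parts$eval) == 0, "empty split partition")
  arch <- default_architecture(config$input_size)
  model <- build_model(arch, config$train)
  model <- train_model(model,
                       load_composites(config, parts$train), parts$train$label,
                       load_composites(config, parts$eval), parts$eval$label)
  dir.create(config$paths$models, recursive = TRUE, showWarnings = FALSE)
  save_model(model, file.path(config$paths$models, "model.rds"))
  write_history(model$history, file.path(config$paths$models, "history.tsv"))
  message(sprintf("train: %d train / %d eval segments, final val accuracy %.4f",
                  nrow(parts$train), nrow(parts$eval),
                  model$history$val_accuracy[nrow(model$history)]))
  invisible(model)
}

#' Pipeline step 5: evaluate on the eval split
#'
#' Recomputes the split (deterministic given the config seed), predicts the
#' eval composites with the saved checkpoint, and writes the confusion
#' counts and the five-score report.
#'
#' @param config a [pipeline_config()]
#' @return list with `report` ([score()] result), `cm`, and the report row
#' @export
cmd_evaluate <- function(config) {
  manifest <- read_manifest(manifest_path(config))
  parts <- split_dataset(manifest, config$split)
  stop_if(nrow(parts$eval) == 0, "empty eval partition")
  model <- load_model(file.path(config$paths$models, "model.rds"))
  pred <- predict_labels(model, load_composites(config, parts$eval))
  cm <- confusion(parts$eval$label, pred)
  report <- score(cm)
  dir.create(config$paths$reports, recursive = TRUE, showWarnings = FALSE)
  row <- report_row(report, config$input_size, config$train$optimizer,
                    config$train$learning_rate)
  utils::write.table(row, file.path(config$paths$reports, "report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn),
                     file.path(config$paths$reports, "confusion.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  message(sprintf("evaluate: accuracy %.2f%% on %d eval segments",
                  100 * report$accuracy, nrow(parts$eval)))
  list(report = report, cm = cm, row = row)
}

#' Run the whole pipeline: simulate, scalogram, tile, train, evaluate
#'
#' Equivalent to calling the five `cmd_*` steps in order on the same
#' config; every artifact path derives from the config alone.
#'
#' @param config a [pipeline_config()]
#' @return the [cmd_evaluate()] result
#' @export
run_pipeline <- function(config) {
  cmd_simulate(config)
  cmd_scalogram(config)
  cmd_tile(config)
  cmd_train(config)
  cmd_evaluate(config)
}

#' In-memory synthetic end-to-end experiment
#'
#' Generates (or reuses) a synthetic dataset, renders scalograms, composes
#' and immediately resizes each composite to the network input size
#' without touching the disk, then trains and evaluates the depthwise CNN.
#' This is the package's fast path for benchmarking the full method; it
#' produces the same reports as the disk pipeline for identical seeds and
#' configurations.
#'
#' @param synthetic a [synthetic_config()]
#' @param dataset optional pre-generated `eeg_dataset` (skips generation)
#' @param input_size network input `(height, width)`, default 100x140
#' @param epochs training epochs, default 15
#' @param train a [train_config()]
#' @param split a [split_spec()]
#' @param cwt a [cwt_params()]
#' @param layout a [tile_layout()]
#' @return list: fitted `model`, `history`, `report`, `cm`, split part
#'   sizes `n_train` / `n_eval`
#' @export
synthetic_experiment <- function(synthetic = synthetic_config(),
                                 dataset = NULL,
                                 input_size = c(100, 140),
                                 epochs = 15,
                                 train = train_config(epochs = epochs),
                                 split = split_spec(),
                                 cwt = cwt_params(),
                                 layout = tile_layout()) {
  ds <- dataset %||% generate_dataset(synthetic)
  imgs <- dataset_composites(ds, input_size, cwt, layout)
  parts <- split_dataset(ds$manifest, split)
  key <- function(m) paste(m$subject_id, m$segment_id)
  all_keys <- key(ds$manifest)
  itrain <- match(key(parts$train), all_keys)
  ieval <- match(key(parts$eval), all_keys)
  arch <- default_architecture(input_size)
  model <- build_model(arch, train)
  model <- train_model(model,
                       imgs[, , , itrain, drop = FALSE], parts$train$label,
                       imgs[, , , ieval, drop = FALSE], parts$eval$label)
  pred <- predict_labels(model, imgs[, , , ieval, drop = FALSE])
  cm <- confusion(parts$eval$label, pred)
  list(model = model, history = model$history, report = score(cm), cm = cm,
       n_train = nrow(parts$train), n_eval = nrow(parts$eval))
}

#' Composite images of a whole dataset, resized for the network
#'
#' For each segment: 35 scalogram tiles, 7x5 composition, bilinear resize
#' to `input_size` with values in `[0, 1]`.
#'
#' @param dataset an `eeg_dataset`
#' @param input_size target `(height, width)`
#' @param cwt a [cwt_params()]
#' @param layout a [tile_layout()]
#' @return array `input_size[1] x input_size[2] x 3 x N`
#' @export
dataset_composites <- function(dataset, input_size = c(100, 140),
                               cwt = cwt_params(), layout = tile_layout()) {
  n <- length(dataset$segments)
  out <- array(0, c(input_size[1], input_size[2], 3, n))
  for (i in seq_len(n)) {
    tiles <- segment_scalograms(dataset$segments[[i]], cwt, layout$tile_size)
    comp <- compose(tiles, layout)
    out[, , , i] <- resize_bilinear(comp / 255, input_size[1], input_size[2])
  }
  out
}
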