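#' Construct a labelled EEG segment
#'
#' @param samples numeric matrix, `n_channels x T` (rows = channels)
#' @param fs sampling rate, Hz; `T` must equal `round(fs)` for the 1-s
#'   segments the pipeline consumes
#' @param label `"epilepsy"` or `"normal"`
#' @param subject_id,segment_id identifiers
#' @return an object of class `eeg_segment`
#' @export
eeg_segment <- function(samples, fs, label, subject_id, segment_id) {
  stop_if(!is.matrix(samples) || !is.numeric(samples), "samples must be a numeric matrix")
  stop_if(any(!is.finite(samples)), "samples must be finite")
  stop_if(!label %in% c("epilepsy", "normal"), "label must be 'epilepsy' or 'normal'")
  structure(list(samples = samples, fs = fs, label = label,
                 subject_id = subject_id, segment_id = segment_id),
            class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> %s/%s [%s], %d channels x %d samples @ %g Hz\n",
              x$subject_id, x$segment_id, x$label,
              nrow(x$samples), ncol(x$samples), x$fs))
  invisible(x)
}

#' @noRd
segment_meta_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Write an EEG segment to disk
#'
#' The canonical on-disk format is a CSV of `T` rows by `n_channels`
#' columns (header = channel names `ch01..`) plus a JSON sidecar
#' (`<stem>.json`) carrying `fs`, `label`, `subject_id` and `segment_id`.
#'
#' @param segment an [eeg_segment()]
#' @param path CSV file path
#' @return `path`, invisibly
#' @export
write_segment <- function(segment, path) {
  stop_if(!inherits(segment, "eeg_segment"), "segment must be an eeg_segment")
  m <- t(segment$samples)
  colnames(m) <- sprintf("ch%02d", seq_len(ncol(m)))
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  meta <- list(fs = segment$fs, label = segment$label,
               subject_id = segment$subject_id, segment_id = segment$segment_id,
               n_channels = nrow(segment$samples))
  jsonlite::write_json(meta, segment_meta_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an EEG segment from disk
#'
#' @param path CSV file path written by [write_segment()]
#' @param format only `"csv"` is supported
#' @param n_channels expected channel count; the paper-faithful pipeline
#'   requires 35
#' @return an [eeg_segment()]
#' @export
read_segment <- function(path, format = "csv", n_channels = 35) {
  stop_if(!identical(format, "csv"), "only the canonical 'csv' format is supported")
  stop_if(!file.exists(path), "segment file not found: ", path)
  m <- as.matrix(utils::read.csv(path, check.names = FALSE))
  stop_if(ncol(m) != n_channels,
          sprintf("expected %d channels, found %d in %s", n_channels, ncol(m), path))
  stop_if(any(!is.finite(m)), "non-finite sample values in ", path)
  mp <- segment_meta_path(path)
  stop_if(!file.exists(mp), "missing metadata sidecar: ", mp)
  meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  eeg_segment(t(m), fs = meta$fs, label = meta$label,
              subject_id = meta$subject_id, segment_id = meta$segment_id)
}

#' Write / read a dataset manifest
#'
#' Tab-separated table with columns subject_id, segment_id, label, path.
#'
#' @param manifest data.frame with those columns
#' @param path file path
#' @return the path (write) or the manifest data.frame (read)
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stop_if(!all(c("subject_id", "segment_id", "label", "path") %in% names(m)),
          "manifest must have columns subject_id, segment_id, label, path")
  m
}

#' Write all segments of a dataset plus its manifest
#'
#' @param dataset an `eeg_dataset` from [generate_dataset()]
#' @param dir output directory (created if needed)
#' @return the dataset with manifest paths filled in, invisibly
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(dataset$segments)) {
    seg <- dataset$segments[[i]]
    p <- file.path(dir, sprintf("%s_%s.csv", seg$subject_id, seg$segment_id))
    write_segment(seg, p)
    dataset$manifest$path[i] <- p
  }
  write_manifest(dataset$manifest, file.path(dir, "manifest.tsv"))
  invisible(dataset)
}

#' Train/eval split specification
#'
#' @param train_fraction fraction of data for training, in (0, 1);
#'   default 0.75 (the remaining 25% serves as the evaluation partition,
#'   used for both validation and test)
#' @param mode `"segment"` (uniform segment-level permutation, the default)
#'   or `"subject"` (whole subjects assigned to one side only, avoiding
#'   subject leakage)
#' @param seed integer seed for the permutation
#' @param three_way when `TRUE`, the held-out partition is further halved
#'   into `validation` and `test`; by default it stays a single `eval`
#'   partition used for both purposes
#' @return an object of class `split_spec`
#' @export
split_spec <- function(train_fraction = 0.75, mode = c("segment", "subject"),
                       seed = 1L, three_way = FALSE) {
  stop_if(!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1,
          "train_fraction must be in (0, 1)")
  mode <- match.arg(mode)
  structure(list(train_fraction = train_fraction, mode = mode,
                 seed = as.integer(seed), three_way = isTRUE(three_way)),
            class = "split_spec")
}

#' Split a manifest into train and eval partitions
#'
#' Segment mode permutes all records uniformly and assigns the first
#' `ceiling(train_fraction * N)` to training. Subject mode permutes
#' subjects within each class and assigns whole subjects to training until
#' the class's train fraction is reached, always leaving at least one
#' subject per class in the eval partition.
#'
#' @param manifest manifest data.frame
#' @param spec a [split_spec()]
#' @return list with elements `train` and `eval`, each a manifest; with
#'   `three_way = TRUE`, elements `train`, `validation` and `test`
#'   (validation/test halve the held-out records, whole subjects in
#'   subject mode)
#' @export
split_dataset <- function(manifest, spec = split_spec()) {
  stop_if(!inherits(spec, "split_spec"), "spec must be a split_spec")
  stop_if(is.null(manifest) || nrow(manifest) == 0, "manifest is empty")
  if (spec$mode == "segment") {
    perm <- with_seed(spec$seed, sample.int(nrow(manifest)))
    n_train <- ceiling(spec$train_fraction * nrow(manifest))
    train_idx <- perm[seq_len(n_train)]
  } else {
    train_idx <- integer(0)
    for (lab in unique(manifest$label)) {
      rows <- which(manifest$label == lab)
      subjects <- unique(manifest$subject_id[rows])
      stop_if(length(subjects) < 2,
              "subject mode needs at least 2 subjects per class (class ", lab, ")")
      ord <- with_seed(derive_seed(spec$seed, match(lab, sort(unique(manifest$label)))),
                       sample(subjects))
      target <- spec$train_fraction * length(rows)
      got <- 0
      for (k in seq_along(ord)) {
        if (got >= target || k == length(ord)) break # keep >= 1 subject for eval
        idx <- rows[manifest$subject_id[rows] == ord[k]]
        train_idx <- c(train_idx, idx)
        got <- got + length(idx)
      }
    }
  }
  eval_idx <- sort(setdiff(seq_len(nrow(manifest)), train_idx))
  train <- manifest[sort(train_idx), , drop = FALSE]
  held <- manifest[eval_idx, , drop = FALSE]
  if (!spec$three_way) {
    return(list(train = train, eval = held))
  }
  if (spec$mode == "segment") {
    perm <- with_seed(derive_seed(spec$seed, 999), sample.int(nrow(held)))
    vi <- sort(perm[seq_len(ceiling(nrow(held) / 2))])
  } else {
    subs <- unique(held$subject_id)
    ord <- with_seed(derive_seed(spec$seed, 999), sample(subs))
    keep <- ord[seq_len(ceiling(length(ord) / 2))]
    vi <- which(held$subject_id %in% keep)
  }
  list(train = train,
       validation = held[vi, , drop = FALSE],
       test = held[-vi, , drop = FALSE])
}
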