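#' Configuration for the synthetic EEG generator
#'
#' Describes a cohort of synthetic subjects, half labelled `"normal"` and
#' half `"epilepsy"`. Normal segments are spatially mixed 1/f^beta
#' background sources with an alpha-band rhythm; epilepsy segments
#' additionally carry a ~3 Hz spike-and-wave discharge on a fixed focal
#' subset of channels, scaled relative to each channel's background RMS.
#' Per-subject segment counts vary, mirroring clinical cohorts where the
#' number of sampled 1-s windows differs between individuals.
#'
#' @param n_subjects_per_class subjects per class (default 40)
#' @param segments_per_subject_range integer `(min, max)`; each subject's
#'   segment count is drawn uniformly from this range (default `c(6, 10)`)
#' @param fs sampling rate in Hz (default 500, giving T = 500 samples/s)
#' @param n_channels electrode count; the paper-faithful pipeline needs 35
#' @param swd_rate spike-and-wave fundamental frequency, Hz (default 3)
#' @param swd_amplitude_ratio epileptiform spike amplitude as a multiple of
#'   the per-channel background RMS (default 4)
#' @param focal_channel_fraction fraction in (0, 1] of channels carrying
#'   the discharge (default 0.5)
#' @param alpha_band `(low, high)` Hz of the background rhythm (default 8-13)
#' @param noise_exponent spectral slope beta of the 1/f^beta background
#' @param seed integer seed; expands to per-subject/per-segment substreams
#' @return an object of class `synthetic_config`
#' @export
synthetic_config <- function(n_subjects_per_class = 40,
                             segments_per_subject_range = c(6L, 10L),
                             fs = 500,
                             n_channels = 35,
                             swd_rate = 3,
                             swd_amplitude_ratio = 4,
                             focal_channel_fraction = 0.5,
                             alpha_band = c(8, 13),
                             noise_exponent = 1,
                             seed = 1L) {
  stop_if(!is_count(n_subjects_per_class), "n_subjects_per_class must be a positive integer")
  rng <- as.integer(segments_per_subject_range)
  stop_if(length(rng) != 2 || rng[1] < 1 || rng[1] > rng[2],
          "segments_per_subject_range must be (min, max) with 1 <= min <= max")
  stop_if(!is.numeric(fs) || fs <= 0, "fs must be positive")
  stop_if(length(alpha_band) != 2 || alpha_band[1] <= 0 || alpha_band[1] >= alpha_band[2],
          "alpha_band must be (low, high) with 0 < low < high")
  stop_if(fs < 2 * alpha_band[2], "fs must be at least twice alpha_band[2] (Nyquist)")
  stop_if(!is_count(n_channels), "n_channels must be a positive integer")
  stop_if(swd_rate <= 0 || swd_rate >= fs / 10, "swd_rate must satisfy 0 < swd_rate < fs/10")
  stop_if(swd_amplitude_ratio <= 0, "swd_amplitude_ratio must be positive")
  stop_if(focal_channel_fraction <= 0 || focal_channel_fraction > 1,
          "focal_channel_fraction must be in (0, 1]")
  stop_if(noise_exponent < 0, "noise_exponent must be non-negative")
  structure(list(
    n_subjects_per_class = as.integer(n_subjects_per_class),
    segments_per_subject_range = rng,
    fs = fs,
    n_channels = as.integer(n_channels),
    swd_rate = swd_rate,
    swd_amplitude_ratio = swd_amplitude_ratio,
    focal_channel_fraction = focal_channel_fraction,
    alpha_band = as.numeric(alpha_band),
    noise_exponent = noise_exponent,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Generate one channel of background ("normal") EEG
#'
#' Spectral synthesis of 1/f^beta noise (random phases, amplitude
#' proportional to f^(-beta/2)) plus a single alpha-band sinusoid with
#' random frequency inside `alpha_band`, random phase, and amplitude 1.5x
#' the noise RMS. The result is standardized to zero mean.
#'
#' @param fs sampling rate, Hz
#' @param duration_s duration in seconds
#' @param alpha_band `(low, high)` Hz
#' @param noise_exponent spectral slope beta
#' @param seed optional integer; when given, the draw is made under a local
#'   RNG stream and the caller's RNG state is untouched
#' @return numeric vector of length `round(fs * duration_s)`
#' @export
generate_background <- function(fs, duration_s, alpha_band = c(8, 13),
                                noise_exponent = 1, seed = NULL) {
  stop_if(!is.numeric(fs) || fs <= 0 || !is.numeric(duration_s) || duration_s <= 0,
          "fs and duration_s must be positive")
  stop_if(fs <= 2 * alpha_band[2], "fs must exceed twice alpha_band[2]")
  if (!is.null(seed)) {
    return(with_seed(seed, generate_background(fs, duration_s, alpha_band, noise_exponent)))
  }
  n <- round(fs * duration_s)
  # one-sided spectrum for bins 1..floor(n/2); bin k maps to frequency k/duration
  nh <- n %/% 2
  f <- seq_len(nh) / duration_s
  amp <- f^(-noise_exponent / 2)
  phase <- stats::runif(nh, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- complex(real = numeric(n))
  full[2:(nh + 1)] <- spec
  if (n %% 2 == 0) full[nh + 1] <- complex(real = amp[nh]) # Nyquist bin real
  if (nh + 2 <= n) {
    idx <- seq(n, nh + 2) # negative-frequency bins, mirrored
    full[idx] <- Conj(full[2:(1 + length(idx))])
  }
  noise <- Re(stats::fft(full, inverse = TRUE)) / n
  rms <- sqrt(mean(noise^2))
  f0 <- stats::runif(1, alpha_band[1], alpha_band[2])
  ph <- stats::runif(1, 0, 2 * pi)
  t <- (seq_len(n) - 1) / fs
  x <- noise + 1.5 * rms * sin(2 * pi * f0 * t + ph)
  x - mean(x)
}

#' Generate one channel of spike-and-wave discharge
#'
#' Periodic complexes at `swd_rate` Hz, the first starting at a random
#' onset phase in `[0, 1/swd_rate)`. Each complex is a sharp Gaussian
#' spike (sigma = 10 ms, peak `amplitude`) followed by a slow half-sine
#' wave of opposite polarity (width 180 ms, peak `0.6 * amplitude`)
#' starting 30 ms (3 sigma) after the spike centre. A 1-s segment at the
#' default 3 Hz therefore contains exactly three spikes.
#'
#' @inheritParams generate_background
#' @param swd_rate complex repetition rate, Hz; must be below `fs / 10`
#' @param amplitude spike peak amplitude (same units as the signal)
#' @param seed optional integer, as in [generate_background()]
#' @return numeric vector of length `round(fs * duration_s)`
#' @export
generate_spike_wave <- function(fs, duration_s, swd_rate = 3, amplitude = 1,
                                seed = NULL) {
  stop_if(!is.numeric(fs) || fs <= 0 || !is.numeric(duration_s) || duration_s <= 0,
          "fs and duration_s must be positive")
  stop_if(swd_rate <= 0 || swd_rate >= fs / 10,
          "swd_rate must satisfy 0 < swd_rate < fs/10")
  if (!is.null(seed)) {
    return(with_seed(seed, generate_spike_wave(fs, duration_s, swd_rate, amplitude)))
  }
  n <- round(fs * duration_s)
  x <- numeric(n)
  if (amplitude == 0) return(x)
  period <- 1 / swd_rate
  onset <- stats::runif(1, 0, period)
  t <- (seq_len(n) - 1) / fs
  sigma <- 0.010
  wave_w <- 0.180
  # the discharge starts at the onset: exactly floor(duration * rate)
  # complexes fall inside the segment (up to right-edge truncation)
  centres <- seq(onset, duration_s, by = period)
  for (tc in centres) {
    x <- x + amplitude * exp(-(t - tc)^2 / (2 * sigma^2))
    ts <- tc + 3 * sigma
    in_wave <- t >= ts & t <= ts + wave_w
    x[in_wave] <- x[in_wave] - 0.6 * amplitude * sin(pi * (t[in_wave] - ts) / wave_w)
  }
  x
}

# subject-level full-rank mixing matrix with unit diagonal dominance:
# identity plus off-diagonal entries rescaled so each row's off-diagonal
# absolute sum is `spread` < 1 (strict diagonal dominance => invertible)
#' @noRd
mixing_matrix <- function(n_channels, spread = 0.5) {
  m <- matrix(stats::rnorm(n_channels^2), n_channels, n_channels)
  diag(m) <- 0
  rs <- rowSums(abs(m))
  rs[rs == 0] <- 1
  m <- m * (spread / rs)
  diag(m) <- 1
  m
}

#' Generate a labelled synthetic EEG dataset
#'
#' For each subject a segment count is drawn uniformly from
#' `segments_per_subject_range`. A subject keeps one spatial mixing matrix
#' (identity plus strictly diagonally dominant off-diagonal mixing) and,
#' for epileptic subjects, one fixed focal channel subset of size
#' `ceiling(focal_channel_fraction * n_channels)`. Normal segments are
#' mixed background sources; epilepsy segments add a shared spike-and-wave
#' discharge to the focal channels, scaled to `swd_amplitude_ratio` times
#' that channel's background RMS. Everything is reproducible from
#' `config$seed` via counter-based substreams.
#'
#' @param config a [synthetic_config()]
#' @return an object of class `eeg_dataset`: a list with `segments` (list
#'   of `eeg_segment` objects) and `manifest` (data.frame with columns
#'   subject_id, segment_id, label, path -- `path` is `NA` until the
#'   segments are written to disk)
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stop_if(!inherits(config, "synthetic_config"), "config must be a synthetic_config")
  nc <- config$n_channels
  n_focal <- ceiling(config$focal_channel_fraction * nc)
  segments <- list()
  rows <- list()
  for (class_idx in 1:2) {
    label <- c("normal", "epilepsy")[class_idx]
    prefix <- c("N", "E")[class_idx]
    for (s in seq_len(config$n_subjects_per_class)) {
      subject_id <- sprintf("%s%03d", prefix, s)
      sub <- with_seed(derive_seed(config$seed, class_idx, s, 0), {
        list(
          # sample() over an explicit vector: a scalar first argument would
          # be read as 1:n and break the min == max case
          n_seg = {
            choices <- seq(config$segments_per_subject_range[1],
                           config$segments_per_subject_range[2])
            choices[sample.int(length(choices), 1)]
          },
          mix = mixing_matrix(nc),
          focal = sort(sample(nc, n_focal))
        )
      })
      for (j in seq_len(sub$n_seg)) {
        samples <- with_seed(derive_seed(config$seed, class_idx, s, j), {
          src <- vapply(seq_len(nc), function(ch) {
            generate_background(config$fs, 1, config$alpha_band, config$noise_exponent)
          }, numeric(round(config$fs)))
          x <- sub$mix %*% t(src) # n_channels x T
          if (label == "epilepsy") {
            swd <- generate_spike_wave(config$fs, 1, config$swd_rate, amplitude = 1)
            for (ch in sub$focal) {
              rms <- sqrt(mean(x[ch, ]^2))
              x[ch, ] <- x[ch, ] + config$swd_amplitude_ratio * rms * swd
            }
          }
          x
        })
        segment_id <- sprintf("s%03d", j)
        seg <- eeg_segment(samples, fs = config$fs, label = label,
                           subject_id = subject_id, segment_id = segment_id)
        segments[[length(segments) + 1]] <- seg
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = subject_id, segment_id = segment_id, label = label,
          path = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  structure(list(segments = segments, manifest = manifest, config = config),
            class = "eeg_dataset")
}

#' @export
print.eeg_dataset <- function(x, ...) {
  tab <- table(x$manifest$label)
  cat(sprintf("<eeg_dataset> %d segments (%s), %d channels, fs = %g Hz\n",
              nrow(x$manifest),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              x$config$n_channels, x$config$fs))
  invisible(x)
}
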