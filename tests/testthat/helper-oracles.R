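# Independent oracles and shared fixtures for the test suite.

# Brute-force dense Riemann-sum CWT of the real Morlet wavelet: the
# normative discretization, summed over every sample with no truncation or
# FFT. Deliberately slow and independent of the package's implementation.
cwt_dense_oracle <- function(x, scales) {
  T <- length(x)
  n <- 0:(T - 1)
  t(vapply(scales, function(a) {
    vapply(0:(T - 1), function(b) {
      sum(x * exp(-((n - b) / a)^2 / 2) * cos(5 * (n - b) / a)) / sqrt(a)
    }, numeric(1))
  }, numeric(T)))
}

# count strict local maxima above a threshold (boundary samples included)
count_peaks_above <- function(x, threshold) {
  n <- length(x)
  left <- c(-Inf, x[-n])
  right <- c(x[-1], -Inf)
  sum(x > threshold & x > left & x >= right)
}

# mean log band power of a 1-s segment, averaged over channels
mean_bandpower <- function(samples, fs, band) {
  T <- ncol(samples)
  freqs <- (seq_len(T) - 1) * fs / T
  keep <- freqs >= band[1] & freqs <= band[2]
  pw <- apply(samples, 1, function(ch) mean(Mod(stats::fft(ch))[keep]^2))
  mean(log(pw))
}

# shared synthetic cohort at the generator's default study conditions;
# generated once per test run (seed frozen up front)
.fixtures <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    .fixtures$cohort <- generate_dataset(synthetic_config(seed = 42L))
  }
  .fixtures$cohort
}

tiny_cohort <- function() {
  if (is.null(.fixtures$tiny)) {
    .fixtures$tiny <- generate_dataset(
      synthetic_config(n_subjects_per_class = 2,
                       segments_per_subject_range = c(2, 2),
                       fs = 250, seed = 7L))
  }
  .fixtures$tiny
}

random_tile <- function(seed, size = c(100, 100)) {
  set.seed(seed)
  array(sample(0:255, prod(size) * 3, replace = TRUE), c(size, 3))
}

# minimal valid architecture for engine-level tests
toy_architecture <- function(input_shape = c(10, 12, 3)) {
  architecture_spec(input_shape = input_shape, layers = list(
    layer_conv2d(3, 2), layer_depthwise(3), layer_maxpool(2),
    layer_flatten(), layer_dense(5, "relu"), layer_dense(1, "sigmoid")))
}
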