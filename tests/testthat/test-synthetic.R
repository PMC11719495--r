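test_that("background generator honours length, determinism and zero mean", {
  x <- generate_background(500, 1, seed = 1)
  expect_length(x, 500)
  expect_equal(mean(x), 0, tolerance = 1e-12)
  expect_identical(x, generate_background(500, 1, seed = 1))
  expect_false(identical(x, generate_background(500, 1, seed = 2)))
  expect_length(generate_background(250, 2, seed = 1), 500)
  expect_error(generate_background(-1, 1), "positive")
  expect_error(generate_background(20, 1, alpha_band = c(8, 13)), "Nyquist|twice")
})

test_that("averaged background spectrum peaks inside the alpha band", {
  fs <- 500
  acc <- numeric(fs)
  for (k in 1:200) {
    x <- generate_background(fs, 1, seed = 1000 + k)
    acc <- acc + Mod(stats::fft(x))^2
  }
  freqs <- 0:(fs - 1) # 1-s segment: bin k = k Hz
  search <- which(freqs >= 2 & freqs <= 40)
  peak <- freqs[search][which.max(acc[search])]
  expect_gte(peak, 8)
  expect_lte(peak, 13)
})

test_that("spike-wave generator produces the classic 3 Hz morphology", {
  expect_identical(generate_spike_wave(500, 1, 3, amplitude = 0), rep(0, 500))
  # exactly swd_rate spike maxima per second above half the spike amplitude
  for (k in 1:20) {
    s <- generate_spike_wave(500, 1, 3, amplitude = 2, seed = k)
    expect_identical(count_peaks_above(s, 1), 3L)
  }
  expect_error(generate_spike_wave(500, 1, swd_rate = 60), "swd_rate")
  # dominant averaged periodogram peak at the fundamental, 3 +- 0.5 Hz
  acc <- numeric(500)
  for (k in 1:100) {
    acc <- acc + Mod(stats::fft(generate_spike_wave(500, 1, 3, 1, seed = 500 + k)))^2
  }
  peak <- (which.max(acc[2:250])) # bin i+1 = i Hz; skip DC
  expect_lte(abs(peak - 3), 0.5)
})

test_that("dataset generation matches the sampled manifest and is reproducible", {
  cfg <- synthetic_config(n_subjects_per_class = 2,
                          segments_per_subject_range = c(3, 3),
                          fs = 250, seed = 3)
  ds <- generate_dataset(cfg)
  expect_equal(nrow(ds$manifest), 12)
  expect_equal(as.vector(table(ds$manifest$label)), c(6, 6))
  expect_length(ds$segments, 12)
  expect_true(all(vapply(ds$segments, function(s) all(dim(s$samples) == c(35, 250)),
                         logical(1))))
  # manifest rows and segment identities line up
  expect_identical(ds$manifest$subject_id,
                   vapply(ds$segments, `[[`, character(1), "subject_id"))
  ds2 <- generate_dataset(cfg)
  expect_identical(ds$segments, ds2$segments)

  # per-subject counts respect the configured range
  cfg2 <- synthetic_config(n_subjects_per_class = 3,
                           segments_per_subject_range = c(2, 5),
                           fs = 250, seed = 11)
  counts <- table(generate_dataset(cfg2)$manifest$subject_id)
  expect_true(all(counts >= 2 & counts <= 5))
})

test_that("counter-based seeding keeps retained subjects stable under subsetting", {
  small <- generate_dataset(synthetic_config(n_subjects_per_class = 2,
                                             segments_per_subject_range = c(2, 2),
                                             fs = 250, seed = 5))
  large <- generate_dataset(synthetic_config(n_subjects_per_class = 3,
                                             segments_per_subject_range = c(2, 2),
                                             fs = 250, seed = 5))
  keep <- large$manifest$subject_id %in% small$manifest$subject_id
  expect_identical(small$segments, large$segments[keep])
})

test_that("epileptic segments carry more power than normal ones", {
  ds <- default_cohort()
  rms <- vapply(ds$segments, function(s) sqrt(mean(s$samples^2)), numeric(1))
  lab <- ds$manifest$label
  expect_gt(mean(rms[lab == "epilepsy"]), mean(rms[lab == "normal"]))
})

test_that("bandpower features separate the classes almost linearly", {
  ds <- default_cohort()
  feats <- t(vapply(ds$segments, function(s) {
    c(delta = mean_bandpower(s$samples, s$fs, c(1, 4)),
      alpha = mean_bandpower(s$samples, s$fs, c(8, 13)))
  }, numeric(2)))
  y <- as.integer(ds$manifest$label == "epilepsy")
  parts <- split_dataset(ds$manifest, split_spec(seed = 42))
  key <- paste(ds$manifest$subject_id, ds$manifest$segment_id)
  itr <- key %in% paste(parts$train$subject_id, parts$train$segment_id)
  fit <- suppressWarnings(
    stats::glm(y ~ delta + alpha, family = stats::binomial(),
               data = data.frame(y = y[itr], feats[itr, , drop = FALSE])))
  pred <- as.integer(stats::predict(fit, newdata = as.data.frame(feats[!itr, , drop = FALSE]),
                                    type = "response") >= 0.5)
  acc <- mean(pred == y[!itr])
  expect_gte(acc, 0.85)
})

test_that("synthetic configuration validates its invariants", {
  expect_error(synthetic_config(segments_per_subject_range = c(3, 2)), "min <= max")
  expect_error(synthetic_config(fs = 20), "Nyquist|twice")
  expect_error(synthetic_config(focal_channel_fraction = 0), "focal")
  expect_error(synthetic_config(swd_rate = 100), "swd_rate")
})
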