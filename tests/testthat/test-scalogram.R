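test_that("the real Morlet mother wavelet evaluates its closed form", {
  expect_identical(morlet_mother(0), 1)
  expect_equal(morlet_mother(-1), morlet_mother(1)) # even function
  expect_equal(morlet_mother(1), 0.17205, tolerance = 1e-5)
  expect_equal(morlet_mother(2), exp(-2) * cos(10), tolerance = 1e-12)
  expect_error(morlet_mother(Inf), "finite")
})

test_that("cwt obeys linearity, zero-signal and contract errors", {
  params <- cwt_params(c(1, 2, 5, 10))
  expect_true(all(cwt(rep(0, 64), params)$coefs == 0))
  set.seed(1)
  x <- rnorm(64)
  expect_equal(cwt(2 * x, params)$coefs, 2 * cwt(x, params)$coefs, tolerance = 1e-12)
  expect_equal(dim(cwt(x, params)$coefs), c(4, 64))
  expect_error(cwt(numeric(0)), "at least 2")
  expect_error(cwt_params(c(0, 1)), "positive")
  expect_error(cwt_params(c(2, 1)), "increasing")
})

test_that("a 25 Hz sinusoid at fs 500 peaks near scale fc * fs / f", {
  tt <- (0:499) / 500
  W <- cwt(sin(2 * pi * 25 * tt))$coefs
  peak_scale <- which.max(rowMeans(abs(W)))
  expect_lte(abs(peak_scale - 0.8125 * 500 / 25), 2) # a* = 16.25
})

test_that("cwt agrees with the PyWavelets morl transform at large scales", {
  # PyWavelets discretizes via finite differences of the integrated
  # wavelet, which departs from the plain Riemann sum at small scales;
  # from scale ~32 upward the two agree up to per-scale normalization.
  sig <- generate_background(500, 1, seed = 3)
  sfile <- tempfile(fileext = ".csv")
  pfile <- tempfile(fileext = ".csv")
  utils::write.table(sig, sfile, row.names = FALSE, col.names = FALSE)
  code <- sprintf(paste0(
    "import numpy as np, pywt; x = np.loadtxt('%s'); ",
    "c, f = pywt.cwt(x, np.arange(32, 101), 'morl'); ",
    "np.savetxt('%s', c, delimiter=',')"), sfile, pfile)
  status <- system2("python", c("-c", shQuote(code)))
  expect_identical(status, 0L)
  P <- as.matrix(utils::read.csv(pfile, header = FALSE))
  W <- cwt(sig, cwt_params(32:100))$coefs
  rc <- vapply(seq_len(nrow(W)), function(s) {
    stats::cor(abs(W[s, ]), abs(P[s, ]), method = "spearman")
  }, numeric(1))
  expect_gt(min(rc), 0.99)
})

test_that("jet colormap matches its piecewise-linear closed form", {
  expect_identical(jet_color(0), cbind(r = 0L, g = 0L, b = 128L))
  expect_identical(jet_color(1), cbind(r = 128L, g = 0L, b = 0L))
  expect_identical(jet_color(0.5), cbind(r = 128L, g = 255L, b = 128L))
  v <- seq(0, 1, by = 0.01)
  rgb <- jet_color(v)
  expect_true(all(rgb >= 0 & rgb <= 255))
  expect_warning(out <- jet_color(c(-0.5, 2)), "clamped")
  expect_identical(out, jet_color(c(0, 1)))
})

test_that("scalogram images are 100x100x3, normalized and scale-invariant", {
  set.seed(3)
  x <- rnorm(250)
  img <- scalogram_image(x, cwt_params(1:40))
  expect_identical(dim(img), c(100L, 100L, 3L))
  expect_true(all(img >= 0 & img <= 255))
  # min-max normalization cancels any global amplitude factor
  expect_identical(img, scalogram_image(5 * x, cwt_params(1:40)))
  # degenerate input: constant field renders uniformly as jet(0)
  flat <- scalogram_image(rep(0, 100), cwt_params(1:10))
  expect_true(all(flat[, , 1] == 0) && all(flat[, , 2] == 0) && all(flat[, , 3] == 128))
})

test_that("rendered PNG bytes are deterministic", {
  set.seed(4)
  x <- rnorm(250)
  img <- scalogram_image(x, cwt_params(1:30))
  p1 <- tempfile(fileext = ".png")
  p2 <- tempfile(fileext = ".png")
  write_image(img, p1)
  write_image(scalogram_image(x, cwt_params(1:30)), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)), readBin(p2, "raw", file.size(p2)))
  expect_identical(read_image(p1), img)
})

test_that("bilinear resize interpolates half-pixel centres exactly", {
  # integer-factor downscale of a constant gradient stays a gradient
  m <- matrix(rep(seq(0, 1, length.out = 10), each = 10), 10, 10, byrow = FALSE)
  out <- resize_bilinear(m, 5, 10)
  expect_equal(dim(out), c(5, 10))
  expect_equal(out[, 1], rep(m[1, 1], 5)) # columns constant along rows
  # same-size resize is the identity under the half-pixel convention
  expect_equal(resize_bilinear(m, 10, 10), m, tolerance = 1e-12)
})
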