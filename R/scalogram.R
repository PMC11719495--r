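#' Real Morlet mother wavelet
#'
#' The conventional real Morlet ("morl") wavelet
#' \eqn{\psi(t) = e^{-t^2/2} \cos(5 t)} with centre angular frequency 5.
#' Its centre frequency in cycles is approximately 0.8125, so for a signal
#' sampled at `fs` Hz a scale `a` responds most strongly near frequency
#' `0.8125 * fs / a`.
#'
#' @param t numeric vector of time points
#' @return `exp(-t^2/2) * cos(5 t)`
#' @export
morlet_mother <- function(t) {
  stop_if(any(!is.finite(t)), "t must be finite")
  exp(-t^2 / 2) * cos(5 * t)
}

#' CWT parameters
#'
#' @param scales ascending positive scales; default `1:100` so the native
#'   scalogram height matches the 100-px tile height before resizing
#' @return an object of class `cwt_params`
#' @export
cwt_params <- function(scales = 1:100) {
  stop_if(length(scales) < 1 || any(scales <= 0) || any(diff(scales) <= 0),
          "scales must be positive and strictly increasing")
  structure(list(scales = as.numeric(scales)), class = "cwt_params")
}

#' Continuous wavelet transform of one channel
#'
#' Discretizes the CWT integral as a Riemann sum with unit sample spacing:
#' \deqn{W(a, b) = a^{-1/2} \sum_{n=0}^{T-1} x[n]\, \psi\!\big((n-b)/a\big)}
#' for shifts `b = 0..T-1`, with the real Morlet wavelet and boundaries
#' handled by truncation (only available samples enter the sum). The sum is
#' evaluated by exact zero-padded FFT convolution with the sampled wavelet
#' kernel, which reproduces the direct sum to machine precision.
#'
#' @param signal numeric vector, length >= 2
#' @param params a [cwt_params()]
#' @return object of class `scalogram_matrix`: list with `coefs`
#'   (`length(scales) x T` matrix) and `scales`
#' @export
cwt <- function(signal, params = cwt_params()) {
  stop_if(!inherits(params, "cwt_params"), "params must be cwt_params")
  stop_if(length(signal) < 2, "signal must have at least 2 samples")
  stop_if(any(!is.finite(signal)), "signal must be finite")
  w <- cwt_stack_cpp(matrix(as.numeric(signal), ncol = 1), params$scales)
  structure(list(coefs = w[, , 1], scales = params$scales),
            class = "scalogram_matrix")
}

#' CWT of all channels of a segment at once
#'
#' Shares the per-scale wavelet kernels across channels; returns an array
#' `length(scales) x T x n_channels`.
#'
#' @param samples numeric matrix `n_channels x T`
#' @param params a [cwt_params()]
#' @return numeric array of coefficients
#' @export
cwt_channels <- function(samples, params = cwt_params()) {
  stop_if(!is.matrix(samples) || ncol(samples) < 2, "samples must be a matrix with T >= 2")
  cwt_stack_cpp(t(samples), params$scales)
}

#' Piecewise-linear jet colormap
#'
#' Maps values in `[0, 1]` to 8-bit RGB by the closed-form piecewise-linear
#' jet approximation: channel c in (r, g, b) uses centre kappa = 3, 2, 1
#' and value `round(255 * clamp(1.5 - |4 v - kappa|, 0, 1))`. This closed
#' form is the package's normative colormap, so rendered images are
#' bit-exactly reproducible without reference to any plotting library.
#'
#' @param v numeric vector; values outside `[0, 1]` are clamped with a warning
#' @return integer matrix `length(v) x 3` with columns r, g, b in `[0, 255]`
#' @export
jet_color <- function(v) {
  if (any(v < 0 | v > 1, na.rm = TRUE)) {
    warning("values outside [0, 1] clamped before colormapping")
    v <- pmin(pmax(v, 0), 1)
  }
  chan <- function(kappa) as.integer(round(255 * pmin(pmax(1.5 - abs(4 * v - kappa), 0), 1)))
  cbind(r = chan(3), g = chan(2), b = chan(1))
}

# linear interpolation matrix (n_out x n_in), half-pixel-centre convention
#' @noRd
interp_matrix <- function(n_in, n_out) {
  pos <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  pos <- pmin(pmax(pos, 0), n_in - 1)
  lo <- floor(pos)
  hi <- pmin(lo + 1, n_in - 1)
  w <- pos - lo
  m <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    m[i, lo[i] + 1] <- m[i, lo[i] + 1] + (1 - w[i])
    m[i, hi[i] + 1] <- m[i, hi[i] + 1] + w[i]
  }
  m
}

#' Bilinear resize of an image or matrix
#'
#' Separable bilinear interpolation with half-pixel-centre sampling (output
#' pixel centre `(i + 0.5)/H_out` maps to input coordinate
#' `(i + 0.5) * H_in / H_out - 0.5`, clamped to the valid range). Axes are
#' stretched independently, so aspect ratio is not preserved.
#'
#' @param img numeric matrix `H x W` or array `H x W x C`
#' @param out_h,out_w output size in pixels
#' @return resized matrix or array of the same number of channels
#' @export
resize_bilinear <- function(img, out_h, out_w) {
  d <- dim(img)
  stop_if(is.null(d) || !(length(d) %in% c(2, 3)), "img must be a matrix or H x W x C array")
  rr <- interp_matrix(d[1], out_h)
  cc <- interp_matrix(d[2], out_w)
  if (length(d) == 2) return(rr %*% img %*% t(cc))
  out <- array(0, c(out_h, out_w, d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- rr %*% img[, , ch] %*% t(cc)
  out
}

# |coefs| -> [0,1] -> jet -> bilinear resize; shared by the single-channel
# and whole-segment renderers. The normalize+jet step runs in compiled
# code (jet_field_cpp), bit-identical to jet_color(). Returns integer
# array out_h x out_w x 3.
#' @noRd
render_scalogram <- function(coefs, out_size) {
  field <- jet_field_cpp(coefs)
  out <- resize_bilinear(field, out_size[1], out_size[2])
  array(as.integer(round(pmin(pmax(out, 0), 255))), dim(out))
}

#' Render one channel's scalogram image
#'
#' Computes `|W(a, b)|`, min-max normalizes per image (a constant
#' coefficient field maps to 0 everywhere), applies the jet colormap, and
#' bilinearly resizes the colour field to `out_size`. Scale index increases
#' downward, time runs left to right. Per-image normalization makes the
#' output invariant to overall signal amplitude.
#'
#' @param signal numeric vector (one channel, typically 1 s)
#' @param params a [cwt_params()]
#' @param out_size `(height, width)` in pixels, default `c(100, 100)`
#' @return integer array `out_size[1] x out_size[2] x 3` in `[0, 255]`
#' @export
scalogram_image <- function(signal, params = cwt_params(), out_size = c(100, 100)) {
  render_scalogram(cwt(signal, params)$coefs, out_size)
}

#' Render scalogram tiles for every channel of a segment
#'
#' @param segment an [eeg_segment()]
#' @param params a [cwt_params()]
#' @param out_size per-tile `(height, width)`, default `c(100, 100)`
#' @return list of `n_channels` integer RGB arrays, in stored channel order
#'   (tile index `i` = position in this order)
#' @export
segment_scalograms <- function(segment, params = cwt_params(), out_size = c(100, 100)) {
  w <- cwt_channels(segment$samples, params)
  lapply(seq_len(dim(w)[3]), function(ch) render_scalogram(w[, , ch], out_size))
}

#' Write / read an 8-bit RGB image as PNG
#'
#' @param img integer array `H x W x 3` in `[0, 255]`
#' @param path PNG file path
#' @return the path (write) or an integer RGB array (read)
#' @export
write_image <- function(img, path) {
  d <- dim(img)
  stop_if(length(d) != 3 || d[3] != 3, "img must be H x W x 3")
  png::writePNG(img / 255, path)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3 && dim(a)[3] == 4) a <- a[, , 1:3] # drop alpha
  array(as.integer(round(a * 255)), dim(a))
}
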