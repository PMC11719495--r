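#' Derive a reproducible sub-seed from a base seed and integer keys
#'
#' A small multiplicative-congruential hash over the base seed and any
#' number of integer keys. Used throughout the package to expand one global
#' seed into independent per-stage / per-subject / per-segment streams, so
#' that regenerating a subset of the data never changes the retained part.
#'
#' @param seed base integer seed
#' @param ... integer keys (stage index, subject index, segment index, ...)
#' @return an integer in `[0, 2^31-2]`
#' @export
derive_seed <- function(seed, ...) {
  keys <- as.double(c(...))
  m <- 2147483647 # 2^31 - 1, keeps everything a valid R integer
  h <- as.double(seed) %% m
  for (k in keys) {
    h <- (h * 48271 + (k + 1) * 9973 + 12345) %% m
  }
  as.integer(h)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' @noRd
stop_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

#' @noRd
is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x == round(x) && x >= 1
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
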