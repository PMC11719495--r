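#' Tile layout for the multichannel composite
#'
#' @param n_cols,n_rows grid shape (default 7 columns x 5 rows)
#' @param tile_size per-tile `(height, width)` in pixels (default 100x100)
#' @return an object of class `tile_layout`
#' @export
tile_layout <- function(n_cols = 7, n_rows = 5, tile_size = c(100, 100)) {
  stop_if(!is_count(n_cols) || !is_count(n_rows), "grid shape must be positive integers")
  stop_if(length(tile_size) != 2 || any(tile_size < 1), "tile_size must be (height, width)")
  structure(list(n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
                 tile_size = as.integer(tile_size),
                 n_tiles = as.integer(n_cols * n_rows)),
            class = "tile_layout")
}

#' Grid position of channel tile i
#'
#' Channel `i` (0-based position in the stored channel order) lands at
#' column `i %% n_cols` and row `floor(i / n_cols)`: row-major filling,
#' x fast, y slow, with pixel (0, 0) at the top-left.
#'
#' @param i 0-based tile index (vectorized), `0 <= i < n_tiles`
#' @param layout a [tile_layout()]
#' @return integer matrix with columns `col`, `row` (0-based)
#' @export
tile_position <- function(i, layout = tile_layout()) {
  stop_if(any(i != floor(i)) || any(i < 0) || any(i >= layout$n_tiles),
          sprintf("tile index must be an integer in [0, %d]", layout$n_tiles - 1))
  cbind(col = as.integer(i %% layout$n_cols),
        row = as.integer(i %/% layout$n_cols))
}

#' Concatenate channel tiles into one composite image
#'
#' Places tile `i` at the pixel block given by [tile_position()]; with the
#' default layout the 35 tiles of 100x100 yield a composite of 500 rows by
#' 700 columns (700 px wide by 500 px high). Tile content is copied
#' verbatim, no resampling.
#'
#' @param tiles list of `n_tiles` integer RGB arrays, each
#'   `tile_size[1] x tile_size[2] x 3`
#' @param layout a [tile_layout()]
#' @return integer array `(n_rows * tile_h) x (n_cols * tile_w) x 3`
#' @export
compose <- function(tiles, layout = tile_layout()) {
  stop_if(!is.list(tiles) || length(tiles) != layout$n_tiles,
          sprintf("need exactly %d tiles, got %d", layout$n_tiles, length(tiles)))
  th <- layout$tile_size[1]
  tw <- layout$tile_size[2]
  out <- array(0L, c(layout$n_rows * th, layout$n_cols * tw, 3))
  for (i in seq_along(tiles) - 1L) {
    tl <- tiles[[i + 1]]
    stop_if(length(dim(tl)) != 3 || !all(dim(tl) == c(th, tw, 3)),
            sprintf("tile %d is not %d x %d x 3", i, th, tw))
    p <- tile_position(i, layout)
    out[p[1, "row"] * th + seq_len(th), p[1, "col"] * tw + seq_len(tw), ] <- tl
  }
  out
}

#' Extract channel tile i from a composite
#'
#' Exact pixel-block slice; inverse of [compose()].
#'
#' @param composite integer RGB array produced by [compose()]
#' @param i 0-based tile index
#' @param layout a [tile_layout()]
#' @return integer array `tile_size[1] x tile_size[2] x 3`
#' @export
extract_tile <- function(composite, i, layout = tile_layout()) {
  th <- layout$tile_size[1]
  tw <- layout$tile_size[2]
  d <- dim(composite)
  stop_if(length(d) != 3 || d[1] != layout$n_rows * th || d[2] != layout$n_cols * tw,
          sprintf("composite must be %d x %d x 3",
                  layout$n_rows * th, layout$n_cols * tw))
  p <- tile_position(i, layout)
  composite[p[1, "row"] * th + seq_len(th), p[1, "col"] * tw + seq_len(tw), , drop = FALSE]
}
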