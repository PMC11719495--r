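test_that("tile_position is a bijection onto the 7x5 grid", {
  pos <- tile_position(0:34)
  expect_identical(pos[1, ], c(col = 0L, row = 0L))
  expect_identical(pos[8, ], c(col = 0L, row = 1L))  # i = 7
  expect_identical(pos[35, ], c(col = 6L, row = 4L)) # i = 34
  expect_equal(nrow(unique(pos)), 35)
  expect_true(all(pos[, "col"] %in% 0:6) && all(pos[, "row"] %in% 0:4))
  expect_error(tile_position(35), "tile index")
  expect_error(tile_position(-1), "tile index")
})

test_that("compose builds a 700-wide by 500-high composite and inverts exactly", {
  tiles <- lapply(1:35, random_tile)
  comp <- compose(tiles)
  expect_identical(dim(comp), c(500L, 700L, 3L))
  for (i in 0:34) {
    expect_identical(extract_tile(comp, i), tiles[[i + 1]])
  }
  # bottom-right block is the last tile
  expect_identical(comp[401:500, 601:700, ], tiles[[35]])
})

test_that("tiling enforces tile count, tile size and composite size contracts", {
  tiles <- lapply(1:35, random_tile)
  expect_error(compose(tiles[1:34]), "35 tiles")
  bad <- tiles
  bad[[3]] <- random_tile(99, size = c(50, 100))
  expect_error(compose(bad), "not 100 x 100")
  expect_error(extract_tile(array(0L, c(400, 700, 3)), 0), "must be 500 x 700")
})

test_that("non-default layouts stay self-consistent", {
  layout <- tile_layout(n_cols = 3, n_rows = 2, tile_size = c(10, 20))
  tiles <- lapply(1:6, function(i) random_tile(i, size = c(10, 20)))
  comp <- compose(tiles, layout)
  expect_identical(dim(comp), c(20L, 60L, 3L))
  for (i in 0:5) expect_identical(extract_tile(comp, i, layout), tiles[[i + 1]])
})
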