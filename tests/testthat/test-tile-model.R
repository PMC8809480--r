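# Tile data model, tile store and composite rendering.

test_that("tile constructor validates its inputs", {
  img <- matrix(0.5, 8, 8)
  t <- tile("t1", "EM_HIGH", img, section_index = 3, stage_xy = c(1, 2))
  expect_s3_class(t, "icat_tile")
  expect_identical(t$section_index, 3L)
  expect_error(tile("", "EM_HIGH", img))
  expect_error(tile("t1", "XRAY", img))
  expect_error(tile("t1", "EM_HIGH", matrix(numeric(0), 0, 0)), "non-empty")
  expect_error(tile("t1", "EM_HIGH", img, pixel_size_nm = -5), "positive")
})

test_that("store rejects duplicate ids and filters by section", {
  img <- matrix(0.5, 8, 8)
  st <- tile_store()
  st <- store_add_tiles(st, "em_high", list(
    tile("a", "EM_HIGH", img, section_index = 0),
    tile("b", "EM_HIGH", img, section_index = 2)))
  expect_error(store_add_tiles(st, "em_high", tile("a", "EM_HIGH", img)),
               "duplicate tile_id")
  expect_identical(store_sections(st, "em_high"), c(0L, 2L))
  expect_length(store_tiles(st, "em_high", z = 2), 1L)
  expect_length(store_tiles(st, "no_such_stack"), 0L)
})

test_that("world bbox follows the transform", {
  # [DERIVED] a 10x20 image (w=20, h=10) translated by (5, 7) spans
  # x in [5, 24], y in [7, 16]
  t <- tile("a", "EM_HIGH", matrix(0, 10, 20),
            transform = affine_translation(5, 7))
  expect_equal(icatr:::tile_world_bbox(t), c(5, 7, 24, 16))
})

test_that("render_composite reproduces a translated tile exactly", {
  set.seed(1)
  img <- matrix(runif(400), 20, 20)
  t <- tile("a", "EM_HIGH", img, transform = affine_translation(3, 4))
  out <- render_composite(list(t), c(3, 4, 22, 13), out_pixel_size_nm = 5)
  # integer translation: bilinear sampling is exact
  expect_equal(out, img[1:10, 1:20])
  # pixels the tile does not cover are zero
  out2 <- render_composite(list(t), c(0, 0, 9, 9), out_pixel_size_nm = 5)
  expect_true(all(out2[1:4, ] == 0))
  expect_equal(out2[5:10, 4:10], img[1:6, 1:7])
})

test_that("painter's order: the last tile wins on overlap", {
  a <- tile("a", "EM_HIGH", matrix(0.2, 10, 10))
  b <- tile("b", "EM_HIGH", matrix(0.9, 10, 10))
  out <- render_composite(list(a, b), c(0, 0, 9, 9), out_pixel_size_nm = 5)
  expect_true(all(out == 0.9))
})

test_that("rendering an empty region errors", {
  t <- tile("a", "EM_HIGH", matrix(0.5, 10, 10))
  expect_error(render_composite(list(t), c(100, 100, 120, 120),
                                out_pixel_size_nm = 5), "no tile intersects")
})

test_that("coarse rendering averages rather than aliases", {
  # a fine checkerboard sampled at 4x coarser grid must come out near the
  # 0.5 mean, not stuck at one phase of the pattern
  img <- outer(1:64, 1:64, function(i, j) (i + j) %% 2)
  t <- tile("a", "EM_HIGH", img)
  out <- render_composite(list(t), c(8, 8, 48, 48), out_pixel_size_nm = 20)
  expect_lt(max(abs(out - 0.5)), 0.05)
})
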