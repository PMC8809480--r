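# Tile store serialization (TIFF tiles + tilespecs.json).

make_store_fixture <- function() {
  set.seed(11)
  img1 <- round(matrix(runif(64 * 64), 64) * 255) / 255
  img2 <- round(matrix(runif(64 * 64), 64) * 255) / 255
  st <- tile_store()
  st <- store_add_tiles(st, "em_high", list(
    tile("t_a", "EM_HIGH", img1, section_index = 0, stage_xy = c(1.5, -2),
         transform = affine2d(1.01, 0.02, -0.02, 0.99, 10, 20)),
    tile("t_b", "EM_HIGH", img2, section_index = 1,
         transform = affine_translation(-3, 4))))
  st <- store_add_tiles(st, "fm", tile("f_a", "FM", img1, channel = "nuclear",
                                       pixel_size_nm = 20))
  st
}

test_that("write/read round-trips the store", {
  dir <- withr::local_tempdir()
  st <- make_store_fixture()
  write_store(st, dir)
  expect_true(file.exists(file.path(dir, "tilespecs.json")))
  rt <- read_store(dir)
  expect_identical(sort(names(rt$stacks)), c("em_high", "fm"))
  a0 <- store_tiles(st, "em_high")[[1]]; a1 <- store_tiles(rt, "em_high")[[1]]
  expect_identical(a1$tile_id, a0$tile_id)
  expect_identical(a1$modality, a0$modality)
  expect_identical(a1$section_index, a0$section_index)
  expect_equal(a1$stage_xy, a0$stage_xy)
  expect_equal(affine_coefs(a1$transform), affine_coefs(a0$transform))
  # images were pre-quantized to 8 bit, so the TIFF round trip is exact
  expect_equal(a1$image, a0$image)
  f <- store_tiles(rt, "fm")[[1]]
  expect_identical(f$channel, "nuclear")
  expect_equal(f$pixel_size_nm, 20)
})

test_that("reading a non-store directory errors", {
  dir <- withr::local_tempdir()
  expect_error(read_store(dir), "not a tile store")
})

test_that("malformed transform records are rejected", {
  dir <- withr::local_tempdir()
  write_store(make_store_fixture(), dir)
  spec <- jsonlite::read_json(file.path(dir, "tilespecs.json"))
  spec$stacks$em_high[[1]]$transform <- list(1, 0, 0)
  jsonlite::write_json(spec, file.path(dir, "tilespecs.json"),
                       auto_unbox = TRUE, digits = NA)
  expect_error(read_store(dir), "malformed record for tile 't_a'")
})

test_that("a missing image file is reported by tile id", {
  dir <- withr::local_tempdir()
  write_store(make_store_fixture(), dir)
  imgs <- list.files(file.path(dir, "tiles"), full.names = TRUE)
  unlink(imgs[grepl("t_b", imgs)])
  expect_error(read_store(dir), "missing image file")
})
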