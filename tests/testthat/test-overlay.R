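# Cross-spatial registration and overlay propagation.

# One shared scenario: a stitched-quality 2x2 montage (tiles at their true
# transforms) plus a coarse low-magnification tile of the same section.
overlay_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    stack <- simulate_serial_stack(1, size = 640, seed = 81)
    sec <- stack$sections$z0
    ts <- simulate_tileset(sec, rows = 2, cols = 2, overlap = 0.15,
                           jitter_sigma = 3, section_index = 0, seed = 82)
    tl <- ts$tiles
    for (i in seq_along(tl)) tl[[i]]$transform <- ts$truth[[tl[[i]]$tile_id]]
    lm <- simulate_lowmag_tile(sec, section_index = 0, seed = 83)
    cache <<- list(section = sec, highmag = tl, lm = lm)
    cache
  }
})

test_that("overlapping high-mag tiles are selected by stage footprint", {
  fx <- overlay_fixture()
  ov <- find_overlapping_highmag(fx$lm$tile, fx$highmag)
  expect_length(ov, 4L)   # the low-mag frame spans the whole 2x2 montage
  other_z <- fx$highmag[[1]]; other_z$section_index <- 7L
  expect_length(find_overlapping_highmag(fx$lm$tile, list(other_z)), 0L)
})

test_that("cross-spatial registration hits within one low-mag pixel", {
  fx <- overlay_fixture()
  T_lw <- register_lowmag_to_montage(fx$lm$tile, fx$highmag)
  expect_gte(attr(T_lw, "n_matches"), 3L)
  n <- nrow(fx$lm$tile$image)
  corners <- rbind(c(0, 0), c(n - 1, 0), c(0, n - 1), c(n - 1, n - 1))
  err <- sqrt(rowSums((affine_apply(T_lw, corners) -
                         affine_apply(fx$lm$truth, corners))^2))
  # one low-magnification pixel = 38/5 = 7.6 world pixels
  expect_lt(max(err), 7.6)
})

test_that("missing overlap and scale mismatch are rejected", {
  fx <- overlay_fixture()
  adrift <- fx$lm$tile
  adrift$stage_xy <- c(10000, 10000) * 5 / 1000
  expect_error(register_lowmag_to_montage(adrift, fx$highmag),
               "no overlapping")
  # lying about the pixel size breaks the scale consistency guard
  liar <- fx$lm$tile
  liar$pixel_size_nm <- 19
  expect_error(register_lowmag_to_montage(liar, fx$highmag),
               "cross-spatial registration failed")
})

test_that("overlay chain composes cross-modal and cross-spatial transforms", {
  T_fm <- affine_similarity(3.4, 0.02, 10, -5)
  T_lw <- affine_similarity(7.6, -0.01, 40, 45)
  ch <- overlay_chain(T_fm, T_lw)
  expect_s3_class(ch, "overlay_chain")
  expect_lt(coef_diff(ch$T_fm_to_world, affine_compose(T_lw, T_fm)), 1e-12)
  expect_error(overlay_chain(T_fm, "not a transform"))
})

test_that("overlay_fm stamps the transform and reports corner error", {
  fm <- tile("fm0", "FM", matrix(0.5, 32, 32), pixel_size_nm = 130)
  T_fm <- affine_similarity(3.4, 0, 10, -5)
  T_lw <- affine_similarity(7.6, 0, 40, 45)
  ch <- overlay_chain(T_fm, T_lw)
  out <- overlay_fm(fm, ch, truth = ch$T_fm_to_world)
  expect_lt(coef_diff(out$transform, ch$T_fm_to_world), 1e-12)
  expect_equal(attr(out, "corner_error_world_px"), rep(0, 4))
  bad <- ch; bad$T_fm_to_emlow <- NULL
  expect_error(overlay_fm(fm, bad), "missing a member transform")
})
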