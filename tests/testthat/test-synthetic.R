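# Synthetic acquisition generators: determinism, metadata consistency and
# emulator faithfulness (the hidden truth really explains the images).

test_that("texture generation is deterministic and well-ranged", {
  t1 <- make_tissue_texture(5, size = 128)
  t2 <- make_tissue_texture(5, size = 128)
  expect_identical(t1, t2)
  expect_true(all(t1$raster >= 0 & t1$raster <= 1))
  expect_identical(dim(t1$raster), c(128L, 128L))
  t3 <- make_tissue_texture(6, size = 128)
  expect_gt(max(abs(t1$raster - t3$raster)), 0.1)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123); ref <- runif(5)
  set.seed(123)
  invisible(make_tissue_texture(5, size = 64))
  invisible(simulate_slide_overview(4, layout = c(2, 2), seed = 2))
  expect_identical(runif(5), ref)
})

test_that("tileset truth explains the tile images", {
  tex <- make_tissue_texture(7, size = 300)
  ts <- simulate_tileset(tex$raster, rows = 2, cols = 2, overlap = 0.15,
                         jitter_sigma = 3, noise_sigma = 0, shading = 0,
                         seed = 8)
  expect_length(ts$tiles, 4L)
  ids <- vapply(ts$tiles, `[[`, "", "tile_id")
  expect_identical(sort(ids), sort(names(ts$truth)))
  for (t in ts$tiles) {
    tru <- ts$truth[[t$tile_id]]
    n <- nrow(t$image)
    px <- cbind(rep(0:(n - 1), times = n), rep(0:(n - 1), each = n))
    loc <- affine_apply(tru, px)
    # the fixed jitter margin must keep every sample inside the section
    expect_true(all(loc >= 0 & loc[, 1] <= ncol(tex$raster) - 1 &
                      loc[, 2] <= nrow(tex$raster) - 1))
    ref <- matrix(icatr:::sample_bilinear(tex$raster, loc[, 1], loc[, 2]),
                  n, n, byrow = TRUE)
    # noise-free, shading-free tiles equal the resampled texture up to
    # 8-bit quantization
    expect_lt(max(abs(t$image - ref)), 0.5 / 255 + 1e-9)
    # the recorded transform is the nominal grid position, not the truth
    expect_false(isTRUE(all.equal(affine_coefs(t$transform),
                                  affine_coefs(tru))))
  }
})

test_that("beam grid and CL acquisition are mutually consistent", {
  g <- beam_spot_grid(3, 3, pitch = 32, center = c(64, 64))
  expect_identical(dim(g$positions), c(9L, 2L))
  expect_equal(g$positions[5, ], c(x = 64, y = 64))
  tru <- affine_similarity(1.05, 0.03, 4, -2)
  sim <- simulate_cl_acquisition(tru, g, fm_size = 128, snr = Inf, seed = 3)
  # [DERIVED] ground-truth spot centers are inv(truth) applied to the grid
  expect_equal(sim$spot_centers_fm,
               affine_apply(affine_invert(tru), g$positions))
  # image peaks near each true center
  for (i in seq_len(9)) {
    cx <- round(sim$spot_centers_fm[i, 1]); cy <- round(sim$spot_centers_fm[i, 2])
    expect_gt(sim$fm_image[cy + 1, cx + 1], 0.5)
  }
})

test_that("slide overview boxes frame bright rectangles", {
  ov <- simulate_slide_overview(9, layout = c(3, 3), seed = 4)
  expect_identical(dim(ov$boxes), c(9L, 4L))
  g <- icatr:::rgb_to_gray(ov$rgb)
  for (i in 1:9) {
    b <- ov$boxes[i, ]
    inside <- g[(b[2] + 1):(b[4] + 1), (b[1] + 1):(b[3] + 1)]
    expect_gt(mean(inside), 0.5)           # section is bright
  }
  expect_lt(mean(g[1:6, ]), 0.2)           # substrate is dark
})

test_that("serial stack skips discarded sections and records drift truth", {
  st <- simulate_serial_stack(8, missing = c(2, 3), size = 96, seed = 5)
  expect_identical(st$present_z, c(0L, 1L, 4L, 5L, 6L, 7L))
  expect_identical(names(st$sections), paste0("z", st$present_z))
  expect_identical(st$missing, c(2L, 3L))
  expect_identical(sort(names(st$truth)), sort(names(st$sections)))
  # after compensating the recorded drift, neighboring sections are nearly
  # the same tissue (only slow decorrelation noise differs)
  d <- c(st$truth$z0$tx - st$truth$z1$tx, st$truth$z0$ty - st$truth$z1$ty)
  px <- cbind(rep(10:85, times = 76), rep(10:85, each = 76))
  a <- icatr:::sample_bilinear(st$sections$z0, px[, 1], px[, 2])
  b <- icatr:::sample_bilinear(st$sections$z1, px[, 1] + d[1], px[, 2] + d[2])
  expect_gt(cor(a, b), 0.9)
  # without drift compensation the fine texture decorrelates
  b0 <- icatr:::sample_bilinear(st$sections$z1, px[, 1], px[, 2])
  expect_lt(cor(a, b0), cor(a, b))
})

test_that("low-magnification tile truth explains the coarse image", {
  tex <- make_tissue_texture(9, size = 400)
  lm <- simulate_lowmag_tile(tex$raster, seed = 10)
  expect_identical(lm$tile$modality, "EM_LOW")
  expect_equal(lm$tile$pixel_size_nm, 38)
  s <- 38 / 5
  expect_equal(sqrt(abs(affine_det(lm$truth))), s, tolerance = 1e-9)
  n <- nrow(lm$tile$image)
  px <- cbind(rep(0:(n - 1), times = n), rep(0:(n - 1), each = n))
  loc <- affine_apply(lm$truth, px)
  ref <- matrix(icatr:::sample_bilinear(icatr:::gauss_blur(tex$raster, 0.5 * s),
                                        loc[, 1], loc[, 2], outside = 0.5),
                n, n, byrow = TRUE)
  expect_gt(cor(as.vector(lm$tile$image), as.vector(ref)), 0.97)
})
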