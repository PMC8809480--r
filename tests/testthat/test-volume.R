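# Depth-search planning, rough z alignment and the 3D solve.

test_that("depth plan enumerates pairs and reports connectivity", {
  p <- build_depth_plan(c(0, 1, 2, 4), depth = 1)
  # [DERIVED] pairs within depth 1: (0,1), (1,2); z=4 is isolated
  expect_equal(unname(p$pairs), rbind(c(0L, 1L), c(1L, 2L)))
  expect_false(p$connected)
  expect_length(p$components, 2L)
  p2 <- build_depth_plan(c(0, 1, 2, 4), depth = 2)
  expect_true(p2$connected)
  expect_error(build_depth_plan(c(0, 1), depth = 0))
})

test_that("min_connecting_depth finds the smallest bridging window", {
  expect_identical(min_connecting_depth(c(0, 1, 2, 3)), 1L)
  expect_identical(min_connecting_depth(c(0, 1, 3, 4)), 2L)
  # [DERIVED] a 5-section hole needs depth 6
  expect_identical(min_connecting_depth(c(0, 7, 8)), 7L)
  expect_identical(min_connecting_depth(c(0, 20), max_depth = 16L),
                   NA_integer_)
})

test_that("rough z alignment recovers serial drift sub-pixel", {
  st <- simulate_serial_stack(4, size = 200, drift_sigma = 4, seed = 71)
  rough <- rough_align_z(st$sections, downsample_factor = 1)
  # map each section into the first section's frame; truth equivalent is
  # truth_z0^-1 o truth_z (world -> z0 frame is inv(truth_z0))
  for (k in names(st$sections)) {
    ref <- affine_compose(affine_invert(st$truth$z0), st$truth[[k]])
    p <- cbind(c(20, 180, 20, 180), c(20, 20, 180, 180))
    err <- sqrt(rowSums((affine_apply(rough[[k]], p) -
                           affine_apply(ref, p))^2))
    expect_lt(max(err), 1)
  }
})

test_that("cross-section matching prunes far-apart tiles", {
  img <- make_tissue_texture(72, size = 96)$raster
  near_a <- tile("a0", "EM_HIGH", img, section_index = 0)
  near_b <- tile("b0", "EM_HIGH", img, section_index = 1)
  far_b <- tile("b1", "EM_HIGH", img, section_index = 1,
                transform = affine_translation(5000, 5000))
  plan <- build_depth_plan(c(0, 1), 1)
  ms <- cross_section_matches(list(z0 = list(near_a),
                                   z1 = list(near_b, far_b)), plan)
  ids <- unlist(lapply(ms, function(m) c(m$tile_id_a, m$tile_id_b)))
  expect_true("b0" %in% ids)
  expect_false("b1" %in% ids)
})

test_that("solve_volume reports disconnected section groups", {
  img <- matrix(0.5, 64, 64)
  tl <- list(tile("s0", "EM_HIGH", img, section_index = 0),
             tile("s1", "EM_HIGH", img, section_index = 1),
             tile("s4", "EM_HIGH", img, section_index = 4))
  m01 <- point_match_set("s0", "s1", cbind(1:3, c(1, 5, 9)),
                         cbind(2:4, c(2, 6, 10)))
  expect_error(solve_volume(tl, list(), list(m01), solver_options()),
               "disconnected across sections.*z=0,1.*z=4.*depth-search")
})

test_that("solve_volume recovers per-section drift from synthetic matches", {
  set.seed(73)
  # two 2x1 montages stacked in z, translation model, exact matches
  sc0 <- synthetic_match_scenario(1, 2, section_index = 0, noise_sd = 0)
  sc1 <- synthetic_match_scenario(1, 2, section_index = 1, noise_sd = 0)
  tiles <- c(sc0$tiles, sc1$tiles)
  truth <- c(sc0$truth, sc1$truth)
  inter <- list()
  for (ida in names(sc0$truth)) for (idb in names(sc1$truth)) {
    pa <- cbind(runif(6, 0, 63), runif(6, 0, 63))
    world <- affine_apply(truth[[ida]], pa)
    pb <- affine_apply(affine_invert(truth[[idb]]), world)
    inter[[length(inter) + 1L]] <- point_match_set(ida, idb, pa, pb,
                                                   weights = rep(0.5, 6))
  }
  sol <- solve_volume(tiles, c(sc0$matches, sc1$matches), inter,
                      solver_options("translation", lambda = 0))
  anchor <- sort(names(sc0$truth))[1]
  gx <- sol[[anchor]]$tx - truth[[anchor]]$tx
  gy <- sol[[anchor]]$ty - truth[[anchor]]$ty
  for (id in names(truth)) {
    expect_lt(abs(sol[[id]]$tx - truth[[id]]$tx - gx), 1e-7)
    expect_lt(abs(sol[[id]]$ty - truth[[id]]$ty - gy), 1e-7)
  }
})

test_that("export_stack renders aligned planes with z metadata", {
  st <- simulate_serial_stack(3, missing = 1, size = 96, seed = 74)
  secs <- list(z0 = st$sections$z0, z2 = st$sections$z2)
  path <- file.path(withr::local_tempdir(), "stack.tif")
  arr <- export_stack(secs, out_pixel_size_nm = 5, path = path)
  expect_identical(dim(arr)[3], 2L)
  expect_identical(attr(arr, "z_indices"), c(0L, 2L))
  expect_identical(attr(arr, "z_spacing_nm"), 100)
  expect_true(file.exists(path))
  planes <- tiff::readTIFF(path, all = TRUE)
  expect_length(planes, 2L)
})
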