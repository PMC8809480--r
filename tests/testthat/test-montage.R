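# Acquisition geometry and the sparse montage solver.

test_that("EM field width honors the FM overlap constraint", {
  # [DERIVED] w_em = w_fm (1 - 2 o): 20% overlap leaves 60% of the FM field
  expect_equal(em_field_width(100, 0.2), 60)
  # [PAPER] a ~233 um FM field with 20% overlap gives the ~140 um EM field
  # of the reference acquisition geometry
  expect_lt(abs(em_field_width(233, 0.2) - 140), 1)
  expect_error(em_field_width(100, 0.5), "no EM field remains")
  expect_error(em_field_width(100, -0.1), ">= 0")
})

test_that("acquisition grid is serpentine with the correct pitch", {
  g <- plan_acquisition_grid(c(0, 0, 250, 150), w_fm = 100, o_fm = 0.2)
  # [DERIVED] pitch 80: ceil(250/80) = 4 columns, ceil(150/80) = 2 rows
  expect_identical(nrow(g), 8L)
  expect_equal(diff(g$x[1:2]), 80)
  # serpentine: second row runs right-to-left
  expect_identical(g$col[g$row == 1], rev(g$col[g$row == 0]))
  # a box smaller than a field yields one centered position
  g1 <- plan_acquisition_grid(c(10, 10, 40, 30), w_fm = 100, o_fm = 0.2)
  expect_identical(nrow(g1), 1L)
  expect_equal(c(g1$x, g1$y), c(25, 20))
})

test_that("candidate neighbors come from dilated stage footprints", {
  img <- matrix(0.5, 100, 100)
  mk <- function(id, x, y) tile(id, "EM_HIGH", img, stage_xy = c(x, y),
                                pixel_size_nm = 5)   # field 0.5 um
  # [DERIVED] 0.5 um fields at pitch 0.4 um overlap laterally; the 10%
  # dilation also captures the diagonal pair
  tl <- list(mk("t00", 0, 0), mk("t01", 0.4, 0), mk("t10", 0, 0.4),
             mk("t11", 0.4, 0.4), mk("far", 5, 5))
  nb <- candidate_neighbors(tl)
  expect_identical(nrow(nb), 6L)
  expect_false("far" %in% c(nb$a, nb$b))
  expect_true(all(nb$a < nb$b))
  expect_error(candidate_neighbors(list(tl[[1]],
    tile("f", "FM", img))), "single modality")
})

test_that("translation montage recovers hidden offsets from noiseless matches", {
  set.seed(51)
  sc <- synthetic_match_scenario(3, 3, noise_sd = 0)
  sol <- solve_montage(sc$tiles, sc$matches,
                       solver_options("translation", lambda = 0))
  # gauge: solution and truth may differ by the anchor's hidden offset
  anchor <- sort(sc$ids)[1]
  gx <- sol[[anchor]]$tx - sc$truth[[anchor]]$tx
  gy <- sol[[anchor]]$ty - sc$truth[[anchor]]$ty
  for (id in sc$ids) {
    expect_lt(abs(sol[[id]]$tx - sc$truth[[id]]$tx - gx), 1e-8)
    expect_lt(abs(sol[[id]]$ty - sc$truth[[id]]$ty - gy), 1e-8)
  }
})

test_that("the anchor tile stays at its initial transform", {
  set.seed(52)
  sc <- synthetic_match_scenario(2, 3)
  opts <- solver_options("translation", anchor = sc$ids[4])
  sol <- solve_montage(sc$tiles, sc$matches, opts)
  init <- sc$tiles[[which(vapply(sc$tiles, `[[`, "", "tile_id") == sc$ids[4])]]
  expect_identical(affine_coefs(sol[[sc$ids[4]]]),
                   affine_coefs(init$transform))
})

test_that("all three models match the dense normal-equations oracle", {
  set.seed(53)
  for (model in c("translation", "rigid", "affine")) {
    sc <- synthetic_match_scenario(2, 3, noise_sd = 0.5)
    anchor <- sort(sc$ids)[1]
    sol <- solve_montage(sc$tiles, sc$matches,
                         solver_options(model, lambda = 0.005,
                                        anchor = anchor))
    ora <- oracle_solve(sc$tiles, sc$matches, model, 0.005, anchor)
    for (id in sc$ids) {
      got <- icatr:::par_from_transform(sol[[id]], model)
      expect_lt(max(abs(got - ora[[id]])), 1e-8)
    }
  }
})

test_that("solution is invariant to match-set permutation", {
  set.seed(54)
  sc <- synthetic_match_scenario(3, 2, noise_sd = 0.4)
  opts <- solver_options("translation", anchor = sort(sc$ids)[1])
  s1 <- solve_montage(sc$tiles, sc$matches, opts)
  s2 <- solve_montage(sc$tiles, rev(sc$matches), opts)
  for (id in sc$ids)
    expect_lt(coef_diff(s1[[id]], s2[[id]]), 1e-9)
})

test_that("stronger regularization pulls tiles toward their stage transforms", {
  set.seed(55)
  sc <- synthetic_match_scenario(2, 2, noise_sd = 0.3)
  dist_to_init <- function(lambda) {
    sol <- solve_montage(sc$tiles, sc$matches,
                         solver_options("translation", lambda = lambda))
    sum(vapply(sc$tiles, function(t)
      coef_diff(sol[[t$tile_id]], t$transform), 0))
  }
  d <- vapply(c(0.001, 0.1, 10, 1000), dist_to_init, 0)
  expect_true(all(diff(d) < 0))
})

test_that("a disconnected montage names its components", {
  set.seed(56)
  sc <- synthetic_match_scenario(1, 2)
  img <- matrix(0.5, 64, 64)
  lonely <- tile("zzz_lonely", "EM_HIGH", img, stage_xy = c(50, 50))
  expect_error(
    solve_montage(c(sc$tiles, list(lonely)), sc$matches,
                  solver_options("translation")),
    "disconnected match graph.*zzz_lonely")
})

test_that("image-based stitching recovers stage jitter sub-pixel", {
  tex <- make_tissue_texture(61, size = 560)
  ts <- simulate_tileset(tex$raster, rows = 2, cols = 2, overlap = 0.15,
                         jitter_sigma = 3, section_index = 0, seed = 62)
  fs <- lapply(ts$tiles, function(t) extract_features(t$image))
  names(fs) <- vapply(ts$tiles, `[[`, "", "tile_id")
  nb <- candidate_neighbors(ts$tiles)
  ms <- lapply(seq_len(nrow(nb)), function(i)
    match_features(fs[[nb$a[i]]], fs[[nb$b[i]]], model = "translation",
                   tile_id_a = nb$a[i], tile_id_b = nb$b[i]))
  ms <- Filter(function(m) nrow(m$pa) > 0, ms)
  expect_gte(length(ms), 4L)
  sol <- solve_montage(ts$tiles, ms, solver_options("translation"))
  anchor <- sort(names(ts$truth))[1]
  gx <- sol[[anchor]]$tx - ts$truth[[anchor]]$tx
  gy <- sol[[anchor]]$ty - ts$truth[[anchor]]$ty
  err <- vapply(names(ts$truth), function(id)
    sqrt((sol[[id]]$tx - ts$truth[[id]]$tx - gx)^2 +
         (sol[[id]]$ty - ts$truth[[id]]$ty - gy)^2), 0)
  expect_lt(max(err), 0.5)
})
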