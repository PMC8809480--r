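# Cross-modal (FM <-> EM-low) registration from cathodoluminescent spots.

test_that("spot detection localizes noise-free spots to centipixel level", {
  g <- beam_spot_grid(3, 3, pitch = 30, center = c(60, 60))
  tru <- affine_similarity(1.02, -0.02, 5, 3)
  sim <- simulate_cl_acquisition(tru, g, fm_size = 128, snr = Inf, seed = 31)
  sp <- detect_spots(sim$fm_image, 9)
  expect_identical(nrow(sp$centroids), 9L)
  # pair each true center with its nearest detection
  err <- apply(sim$spot_centers_fm, 1, function(p)
    min(sqrt(rowSums(sweep(sp$centroids, 2, p)^2))))
  expect_lt(max(err), 0.05)
})

test_that("registration recovers the transform within 0.1 FM px at SNR 50", {
  g <- beam_spot_grid(3, 3, pitch = 30, center = c(60, 60))
  set.seed(32)
  for (k in 1:5) {
    # misalignment range of the integrated microscope: near-unit scale and
    # a few degrees of rotation (the square spot grid limits the rotation
    # capture range of the grid assignment to roughly +/- 0.15 rad)
    tru <- affine_similarity(runif(1, 0.9, 1.1), runif(1, -0.1, 0.1),
                             runif(1, -8, 8), runif(1, -8, 8))
    sim <- simulate_cl_acquisition(tru, g, fm_size = 128, snr = 50,
                                   seed = 320 + k)
    T <- register_cross_modal(sim$fm_image, g)
    # error measured where it matters: over the FM frame spot support,
    # converted back to FM pixels through the true scale
    pts <- sim$spot_centers_fm
    err <- sqrt(rowSums((affine_apply(T, pts) - affine_apply(tru, pts))^2))
    scale <- sqrt(abs(affine_det(tru)))
    expect_lt(max(err) / scale, 0.1)
  }
})

test_that("degenerate correspondence inputs are rejected", {
  g <- beam_spot_grid(3, 3, pitch = 30, center = c(60, 60))
  expect_error(detect_spots(matrix(0.05, 96, 96), 9), "no CL spots found")
  two <- structure(list(centroids = cbind(c(10, 20), c(10, 20))),
                   class = "spot_detections")
  expect_error(match_grid(two, g), "degenerate CL correspondence")
})

test_that("matching survives a missing and a spurious spot", {
  g <- beam_spot_grid(3, 3, pitch = 30, center = c(60, 60))
  tru <- affine_similarity(1.0, 0.1, 2, -3)
  centers <- affine_apply(affine_invert(tru), g$positions)
  perturbed <- rbind(centers[-5, ], c(5, 5))   # drop center spot, add junk
  sp <- structure(list(centroids = perturbed), class = "spot_detections")
  m <- match_grid(sp, g)
  expect_gte(nrow(m$pa), 6)
  T <- fit_affine(m)
  err <- sqrt(rowSums((affine_apply(T, centers) - g$positions)^2))
  expect_lt(max(err), 0.1)
})
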