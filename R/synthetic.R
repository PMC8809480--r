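# Synthetic acquisition generators with known ground truth.
#
# The microscope is emulated end to end: tissue-like section textures,
# fluorescence channels, tile grids with hidden stage jitter, grids of
# cathodoluminescent spots, slide overviews, and serial-section stacks with
# cumulative drift and discarded sections. All pixel-size ratios honor the
# reference acquisition geometry (EM high 5 nm/px, EM low 38 nm/px, FM
# coarser still, slide overview ~7 um/px), at scaled-down image sizes.
# Every generator is deterministic under a fixed seed; a single global seed
# fans out to per-component seeds by stable hashing (see derive_seed), so
# regenerating one fixture does not shift the random stream of another.

norm01 <- function(m) {
  r <- range(m)
  if (r[2] - r[1] < 1e-12) return(m * 0)
  (m - r[1]) / (r[2] - r[1])
}

#' Generate a tissue-like texture with nucleus and granule masks
#'
#' Band-limited noise background (the extracellular/cytoplasm matrix), dark
#' elliptical nuclei, and fine granular speckle emulating secretory granules.
#' The masks feed the fluorescence channel simulator; the raster feeds the EM
#' tile simulators.
#'
#' @param seed Integer seed (deterministic, bit-identical on repeat).
#' @param size Side length in pixels (>= 256 for realistic structure; smaller
#'   sizes are accepted for quick fixtures).
#' @param nucleus_density Expected nuclei per pixel^2 (default 6e-5).
#' @return List with \code{raster} (matrix in [0,1]), \code{nucleus_mask},
#'   \code{granule_mask} (logical matrices), \code{n_nuclei}, \code{seed}.
#' @export
make_tissue_texture <- function(seed, size = 512L, nucleus_density = 6e-5) {
  with_seed(derive_seed(seed, "tissue"), {
    h <- w <- as.integer(size)
    bg <- 0.45 + 0.35 * (norm01(gauss_blur(matrix(rnorm(h * w), h, w), 18)) - 0.5) +
                 0.30 * (norm01(gauss_blur(matrix(rnorm(h * w), h, w), 6)) - 0.5) +
                 0.60 * (norm01(gauss_blur(matrix(rnorm(h * w), h, w), 2.5)) - 0.5) +
                 0.50 * (norm01(gauss_blur(matrix(rnorm(h * w), h, w), 1.2)) - 0.5)
    # granular speckle: small bright/dark discs (secretory granules, ER)
    n_gran <- rpois(1, 4e-3 * h * w)
    gmask <- matrix(FALSE, h, w)
    if (n_gran > 0) {
      gx <- runif(n_gran, 2, w - 3); gy <- runif(n_gran, 2, h - 3)
      gr <- runif(n_gran, 1, 3.5)
      gs <- sample(c(-1, 1), n_gran, TRUE) * runif(n_gran, 0.15, 0.45)
      for (i in seq_len(n_gran)) {
        xs <- max(1, floor(gx[i] - 3)):min(w, ceiling(gx[i] + 3))
        ys <- max(1, floor(gy[i] - 3)):min(h, ceiling(gy[i] + 3))
        DX <- outer(rep(1, length(ys)), xs - 1 - gx[i])
        DY <- outer(ys - 1 - gy[i], rep(1, length(xs)))
        d2 <- DX^2 + DY^2
        soft <- exp(-d2 / (2 * (gr[i] / 1.5)^2))
        bg[ys, xs] <- bg[ys, xs] + gs[i] * soft
        gmask[ys, xs] <- gmask[ys, xs] | (d2 <= gr[i]^2 & gs[i] > 0)
      }
    }
    # nuclei: dark soft-edged ellipses
    n_nuc <- rpois(1, nucleus_density * h * w)
    nmask <- matrix(FALSE, h, w)
    if (n_nuc > 0) {
      cx <- runif(n_nuc, 0.1 * w, 0.9 * w); cy <- runif(n_nuc, 0.1 * h, 0.9 * h)
      ax <- runif(n_nuc, 0.02 * size, 0.045 * size)
      ratio <- runif(n_nuc, 0.6, 1); th <- runif(n_nuc, 0, pi)
      for (i in seq_len(n_nuc)) {
        a <- ax[i]; b <- ax[i] * ratio[i]
        r <- ceiling(a) + 2L
        xs <- max(1, floor(cx[i] - r)):min(w, ceiling(cx[i] + r))
        ys <- max(1, floor(cy[i] - r)):min(h, ceiling(cy[i] + r))
        DX <- outer(rep(1, length(ys)), xs - 1 - cx[i])
        DY <- outer(ys - 1 - cy[i], rep(1, length(xs)))
        U <- ( cos(th[i]) * DX + sin(th[i]) * DY) / a
        V <- (-sin(th[i]) * DX + cos(th[i]) * DY) / b
        q <- U^2 + V^2
        soft <- pmax(0, pmin(1, (1.15 - q) / 0.3))
        bg[ys, xs] <- bg[ys, xs] * (1 - 0.55 * soft) +
                      0.12 * soft * (1 + 0.3 * (q - 0.5))
        nmask[ys, xs] <- nmask[ys, xs] | (q <= 1)
      }
    }
    list(raster = pmin(pmax(bg, 0), 1), nucleus_mask = nmask,
         granule_mask = gmask, n_nuclei = n_nuc, seed = seed)
  })
}

#' Simulate a fluorescence channel from texture ground truth
#'
#' The nuclear channel is the blurred nucleus mask (a DNA stain); the label
#' channel is a blurred random subset of the granule speckle (an
#' immunofluorescence label marking a granule population). The FM raster is
#' rendered coarser than the EM texture by \code{fm_factor}.
#'
#' @param texture Output of \code{\link{make_tissue_texture}}.
#' @param channel \code{"nuclear"} or \code{"label"}.
#' @param fm_factor Integer downsampling factor EM grid -> FM grid.
#' @param blur_sigma Gaussian PSF sigma in FM pixels.
#' @param seed Integer seed.
#' @return FM raster matrix in [0,1].
#' @export
simulate_fm_channel <- function(texture, channel = c("nuclear", "label"),
                                fm_factor = 4L, blur_sigma = 4, seed = 1L) {
  channel <- match.arg(channel)
  with_seed(derive_seed(seed, paste0("fm_", channel)), {
    mask <- if (channel == "nuclear") texture$nucleus_mask else {
      gm <- texture$granule_mask
      sel <- gm & (matrix(runif(length(gm)), nrow(gm)) < 0.6)
      sel
    }
    m <- downsample_mean(mask * 1, fm_factor)
    sig <- gauss_blur(m, blur_sigma)
    img <- 0.08 + 0.85 * sig / max(max(sig), 1e-9)
    img <- img + matrix(rnorm(length(img), 0, 0.01), nrow(img))
    pmin(pmax(img, 0), 1)
  })
}

#' Simulate a tile-grid acquisition over a section raster
#'
#' Crops a rows-by-cols grid of tiles from a section raster. Each tile's true
#' origin is the nominal serpentine grid position plus hidden Gaussian stage
#' jitter; the recorded stage coordinates are the nominal positions, so the
#' jitter is what stitching must recover. Per-tile Gaussian noise and a
#' linear shading ramp emulate detector noise and beam/illumination falloff.
#'
#' @param section Numeric matrix, the full-resolution section raster.
#' @param rows,cols Grid shape.
#' @param overlap Nominal overlap fraction between neighboring tiles.
#' @param jitter_sigma Stage jitter standard deviation (pixels).
#' @param noise_sigma Additive Gaussian noise sigma (intensity units).
#' @param shading Amplitude of the linear shading ramp (fractional).
#' @param pixel_size_nm Tile pixel size metadata (default 5, EM high).
#' @param section_index z index stamped on the tiles.
#' @param seed Integer seed.
#' @return List: \code{tiles} (list of \code{icat_tile} with stage-derived
#'   nominal transforms), \code{truth} (per-tile true \code{affine2d} into
#'   the section frame), \code{tile_size}, \code{pitch}, \code{seed}.
#' @export
simulate_tileset <- function(section, rows = 2L, cols = 2L, overlap = 0.125,
                             jitter_sigma = 4, noise_sigma = 0.01,
                             shading = 0.05, pixel_size_nm = 5,
                             section_index = 0L, seed = 1L) {
  with_seed(derive_seed(seed, paste0("tileset_z", section_index)), {
    H <- nrow(section); W <- ncol(section)
    margin <- 3 * jitter_sigma + 2
    # tiles (plus jitter margins on both sides) must stay inside the section
    tw <- floor((min(W, H) - 2 * margin) /
                  (1 + (max(rows, cols) - 1) * (1 - overlap))) - 1L
    if (tw < 16L) stop("section too small for the requested tile grid")
    pitch <- tw * (1 - overlap)
    tiles <- list(); truth <- list()
    for (r in seq_len(rows) - 1L) {
      cs <- seq_len(cols) - 1L
      if (r %% 2L == 1L) cs <- rev(cs)   # serpentine acquisition order
      for (cc in cs) {
        nom <- c(margin + cc * pitch, margin + r * pitch)
        tru <- nom + rnorm(2, 0, jitter_sigma)
        xs <- tru[1] + 0:(tw - 1L); ys <- tru[2] + 0:(tw - 1L)
        loc <- cbind(rep(xs, each = tw), rep(ys, times = tw))
        img <- matrix(sample_bilinear(section, loc[, 1], loc[, 2],
                                      outside = 0.5), tw, tw)
        ramp_dir <- runif(1, 0, 2 * pi)
        RX <- matrix((0:(tw - 1)) / tw - 0.5, tw, tw, byrow = TRUE)
        RY <- matrix((0:(tw - 1)) / tw - 0.5, tw, tw)
        img <- img * (1 + shading * (cos(ramp_dir) * RX + sin(ramp_dir) * RY))
        img <- img + matrix(rnorm(tw * tw, 0, noise_sigma), tw, tw)
        img <- round(pmin(pmax(img, 0), 1) * 255) / 255
        id <- sprintf("t_z%03d_r%d_c%d", section_index, r, cc)
        tiles[[id]] <- tile(id, "EM_HIGH", img, section_index = section_index,
                            stage_xy = nom * pixel_size_nm / 1000,
                            pixel_size_nm = pixel_size_nm,
                            transform = affine_translation(nom[1], nom[2]))
        truth[[id]] <- affine_translation(tru[1], tru[2])
      }
    }
    list(tiles = unname(tiles), truth = truth, tile_size = tw, pitch = pitch,
         seed = seed)
  })
}

#' Simulate a low-magnification EM tile over a section
#'
#' Samples the section raster (assumed at the 5 nm world grid) onto a coarse
#' low-magnification grid under a hidden similarity transform: the true
#' scale is the pixel-size ratio (38 / 5 = 7.6 by default) with a small
#' rotation and offset, while the recorded transform is a pure stage-derived
#' scaled translation a few world pixels off. The section is low-passed at
#' half the sampling period before point sampling so the coarse tile is
#' band-limited like a real detector image.
#'
#' @param section Numeric matrix at world resolution.
#' @param pixel_size_nm Low-mag pixel size (default 38).
#' @param world_pixel_size_nm World pixel size (default 5).
#' @param rotation_sd Hidden rotation sigma in radians.
#' @param offset_sd Hidden translation sigma in world pixels.
#' @param noise_sigma Additive noise sigma.
#' @param section_index z index stamped on the tile.
#' @param seed Integer seed.
#' @return List: \code{tile} (an EM_LOW \code{icat_tile} carrying the
#'   nominal transform), \code{truth} (the hidden \code{affine2d} low-mag
#'   pixels -> world pixels), \code{seed}.
#' @export
simulate_lowmag_tile <- function(section, pixel_size_nm = 38,
                                 world_pixel_size_nm = 5,
                                 rotation_sd = 0.01, offset_sd = 3,
                                 noise_sigma = 0.01, section_index = 0L,
                                 seed = 1L) {
  with_seed(derive_seed(seed, paste0("lowmag_z", section_index)), {
    s <- pixel_size_nm / world_pixel_size_nm
    n <- floor(min(dim(section)) / s) - 2L
    if (n < 16L) stop("section too small for a low-magnification tile")
    th <- rnorm(1, 0, rotation_sd)
    nom_off <- c(s, s)
    off <- nom_off + rnorm(2, 0, offset_sd)
    truth <- affine2d(s * cos(th), -s * sin(th), s * sin(th), s * cos(th),
                      off[1], off[2])
    blurred <- gauss_blur(section, 0.5 * s)
    px <- cbind(rep(0:(n - 1L), times = n), rep(0:(n - 1L), each = n))
    loc <- affine_apply(truth, px)
    img <- matrix(sample_bilinear(blurred, loc[, 1], loc[, 2], outside = 0.5),
                  n, n, byrow = TRUE)
    img <- img + matrix(rnorm(n * n, 0, noise_sigma), n, n)
    img <- round(pmin(pmax(img, 0), 1) * 255) / 255
    tl <- tile(sprintf("lm_z%03d", section_index), "EM_LOW", img,
               section_index = section_index,
               stage_xy = nom_off * world_pixel_size_nm / 1000,
               pixel_size_nm = pixel_size_nm,
               transform = affine2d(s, 0, 0, s, nom_off[1], nom_off[2]))
    list(tile = tl, truth = truth, seed = seed)
  })
}

#' Construct a beam-spot grid
#'
#' Known electron-beam dwell positions (in the low-magnification EM tile's
#' local pixel frame) at which cathodoluminescent spots are excited.
#'
#' @param rows,cols Grid shape.
#' @param pitch Spacing in EM-low pixels.
#' @param center Grid center c(x, y) in EM-low pixels.
#' @return Object of class \code{beam_spot_grid}: \code{positions} (n-by-2),
#'   \code{shape}, \code{pitch}.
#' @export
beam_spot_grid <- function(rows = 3L, cols = 3L, pitch = 32, center = c(0, 0)) {
  gx <- (seq_len(cols) - (cols + 1) / 2) * pitch + center[1]
  gy <- (seq_len(rows) - (rows + 1) / 2) * pitch + center[2]
  pos <- cbind(x = rep(gx, times = rows), y = rep(gy, each = cols))
  stopifnot(!anyDuplicated(pos))
  structure(list(positions = pos, shape = c(rows, cols), pitch = pitch),
            class = "beam_spot_grid")
}

#' Simulate a cathodoluminescent spot acquisition
#'
#' Renders the FM camera frame recorded while the electron beam dwells on a
#' grid of positions: each beam position, mapped through the inverse of the
#' true FM-to-EM-low transform, produces a Gaussian spot on the FM camera.
#' Additive Gaussian noise sets the SNR (peak amplitude / noise sigma).
#'
#' @param truth \code{affine2d} mapping FM pixels to EM-low pixels (the
#'   transform cross-modal registration must recover).
#' @param grid A \code{beam_spot_grid} (positions in EM-low pixels).
#' @param fm_size FM frame side length in pixels.
#' @param spot_sigma Spot PSF sigma in FM pixels.
#' @param snr Peak signal-to-noise ratio; \code{Inf} for noise-free.
#' @param seed Integer seed.
#' @return List: \code{fm_image}, \code{grid}, \code{truth},
#'   \code{spot_centers_fm} (ground-truth FM-frame spot centers).
#' @export
simulate_cl_acquisition <- function(truth, grid, fm_size = 128L,
                                    spot_sigma = 2, snr = 50, seed = 1L) {
  with_seed(derive_seed(seed, "cl"), {
    inv <- affine_invert(truth)
    centers <- affine_apply(inv, grid$positions)
    img <- matrix(0, fm_size, fm_size)
    X <- matrix(0:(fm_size - 1), fm_size, fm_size, byrow = TRUE)
    Y <- matrix(0:(fm_size - 1), fm_size, fm_size)
    amp <- 0.8
    for (i in seq_len(nrow(centers)))
      img <- img + amp * exp(-((X - centers[i, 1])^2 + (Y - centers[i, 2])^2) /
                               (2 * spot_sigma^2))
    img <- img + 0.05
    if (is.finite(snr))
      img <- img + matrix(rnorm(fm_size^2, 0, amp / snr), fm_size)
    list(fm_image = pmin(pmax(img, 0), 1), grid = grid, truth = truth,
         spot_centers_fm = centers)
  })
}

#' Simulate a slide-overview image of serial sections
#'
#' An RGB raster emulating the reflected-light digital microscope overview of
#' a section array on an ITO-coated slide: a dark substrate with bright,
#' lightly textured section rectangles placed on a collision-free grid with
#' positional jitter.
#'
#' @param n_sections Number of sections (placed row-major on the layout).
#' @param layout c(rows, cols) grid; must hold \code{n_sections}.
#' @param cell Cell size in overview pixels (each section sits in one cell).
#' @param seed Integer seed.
#' @return List: \code{rgb} (h-by-w-by-3 array in [0,1]), \code{boxes}
#'   (n-by-4 matrix xmin/ymin/xmax/ymax, overview pixels, 0-based),
#'   \code{pixel_size_um} (7).
#' @export
simulate_slide_overview <- function(n_sections = 9L, layout = c(3L, 3L),
                                    cell = 72L, seed = 1L) {
  stopifnot(n_sections >= 1L, prod(layout) >= n_sections)
  with_seed(derive_seed(seed, "overview"), {
    h <- layout[1] * cell + 16L; w <- layout[2] * cell + 16L
    g <- 0.12 + 0.02 * matrix(rnorm(h * w), h, w)
    boxes <- matrix(NA_real_, n_sections, 4,
                    dimnames = list(NULL, c("xmin", "ymin", "xmax", "ymax")))
    for (i in seq_len(n_sections) - 1L) {
      r <- i %/% layout[2]; cc <- i %% layout[2]
      sw <- round(runif(1, 0.50, 0.60) * cell)
      sh <- round(runif(1, 0.50, 0.60) * cell)
      x0 <- 8L + cc * cell + round(runif(1, 0.05, 0.35) * cell)
      y0 <- 8L + r * cell + round(runif(1, 0.05, 0.35) * cell)
      xs <- x0:(x0 + sw - 1L); ys <- y0:(y0 + sh - 1L)
      tex <- 0.65 + 0.06 * matrix(rnorm(sh * sw), sh, sw) +
        0.05 * sin(outer(ys, rep(1, sw)) / 5)
      g[ys + 1L, xs + 1L] <- tex
      boxes[i + 1L, ] <- c(x0, y0, x0 + sw - 1L, y0 + sh - 1L)
    }
    g <- pmin(pmax(g, 0), 1)
    rgb <- array(0, c(h, w, 3))
    rgb[, , 1] <- g * 0.9; rgb[, , 2] <- g; rgb[, , 3] <- g * 1.0
    list(rgb = pmin(rgb, 1), boxes = boxes, pixel_size_um = 7, seed = seed)
  })
}

#' Simulate a serial-section stack with drift and discarded sections
#'
#' Consecutive sections share the base texture with per-section decorrelation
#' noise (structure changes slowly through depth at 100 nm thickness) and a
#' cumulative random-walk drift emulating section placement on the substrate.
#' Discarded sections are absent from the output rasters but recorded in the
#' metadata, exactly as physically lost sections are absent from an array.
#'
#' @param n_sections Total number of sections cut.
#' @param missing Integer vector of discarded z indices (0-based).
#' @param size Section raster side length in pixels.
#' @param drift_sigma Per-section drift step sigma (pixels).
#' @param decorrelation Amplitude of per-section structure change.
#' @param seed Integer seed.
#' @return List: \code{sections} (named list "z<k>" -> raster, present only),
#'   \code{present_z} (0-based indices), \code{missing},
#'   \code{truth} (named list of true \code{affine2d} section-to-world),
#'   \code{n_sections}, \code{seed}.
#' @export
simulate_serial_stack <- function(n_sections, missing = integer(0),
                                  size = 160L, drift_sigma = 3,
                                  decorrelation = 0.04, seed = 1L) {
  missing <- sort(as.integer(missing))
  stopifnot(all(missing >= 0), all(missing < n_sections))
  base_size <- size + 8L * ceiling(drift_sigma * sqrt(max(n_sections, 1))) + 32L
  tex <- make_tissue_texture(derive_seed(seed, "stack_base"), size = base_size)
  with_seed(derive_seed(seed, "stack"), {
    margin <- (base_size - size) / 2
    drift <- matrix(rnorm(2 * n_sections, 0, drift_sigma), ncol = 2)
    drift[1, ] <- 0
    cum <- matrix(apply(drift, 2, cumsum), ncol = 2)
    # clamp cumulative drift so sections never leave the base texture
    cum <- pmin(pmax(cum, -margin + 1), margin - 1)
    sections <- list(); truth <- list()
    raster <- tex$raster
    for (z in seq_len(n_sections) - 1L) {
      raster <- pmin(pmax(raster + decorrelation *
        gauss_blur(matrix(rnorm(base_size^2), base_size), 1.5), 0), 1)
      if (z %in% missing) next
      off <- margin + cum[z + 1L, ]
      xs <- off[1] + 0:(size - 1L); ys <- off[2] + 0:(size - 1L)
      loc <- cbind(rep(xs, each = size), rep(ys, times = size))
      img <- matrix(sample_bilinear(raster, loc[, 1], loc[, 2], outside = 0.5),
                    size, size)
      img <- round(pmin(pmax(img, 0), 1) * 255) / 255
      key <- paste0("z", z)
      sections[[key]] <- img
      truth[[key]] <- affine_translation(off[1], off[2])
    }
    list(sections = sections,
         present_z = setdiff(seq_len(n_sections) - 1L, missing),
         missing = missing, truth = truth,
         n_sections = n_sections, seed = seed)
  })
}
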