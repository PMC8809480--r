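# Cross-spatial registration and fluorescence overlay propagation.
#
# The low-magnification EM tile is the proxy that carries the fluorescence
# overlay to full resolution: it is registered onto the stitched
# high-magnification montage by feature matching against a composite
# rendered at the low-magnification scale, and the resulting transform is
# composed with the cross-modal (CL) transform to place each FM tile in the
# world frame. Inside low-magnification footprints the overlay accuracy is
# bounded by the low-magnification pixel size; in the gaps between
# footprints the transform is extrapolated and the error grows.

# World-pixel footprint of a tile from its stage coordinates alone
# (stage_xy um = position of the local origin pixel).
stage_footprint_world <- function(t, world_pixel_size_nm = 5) {
  o <- t$stage_xy * 1000 / world_pixel_size_nm
  sc <- t$pixel_size_nm / world_pixel_size_nm
  c(o[1], o[2], o[1] + (ncol(t$image) - 1) * sc, o[2] + (nrow(t$image) - 1) * sc)
}

#' High-magnification tiles overlapping a low-magnification tile
#'
#' Selects, by stage coordinates, the high-magnification tiles whose world
#' footprint intersects the low-magnification tile's stage footprint
#' (closed-footprint convention: tiles sharing only an edge are included).
#'
#' @param emlow_tile An EM_LOW \code{icat_tile}.
#' @param highmag List of EM_HIGH \code{icat_tile} of the same section, with
#'   solved montage transforms.
#' @param world_pixel_size_nm World pixel size (default 5).
#' @return The overlapping subset of \code{highmag} (possibly empty).
#' @export
find_overlapping_highmag <- function(emlow_tile, highmag,
                                     world_pixel_size_nm = 5) {
  fp <- stage_footprint_world(emlow_tile, world_pixel_size_nm)
  same_z <- vapply(highmag, function(t)
    t$section_index == emlow_tile$section_index, NA)
  Filter(function(t) box_intersects(tile_world_bbox(t), fp), highmag[same_z])
}

#' Register a low-magnification tile onto the stitched montage
#'
#' Renders a composite of the overlapping high-magnification tiles at the
#' low-magnification pixel scale over the low-mag tile's stage footprint,
#' extracts and matches features between the low-mag tile and the
#' composite, and fits the affine transform mapping low-magnification
#' pixels into the world frame. The fitted scale must agree with the
#' nominal pixel-size ratio (38/5 = 7.6 in the reference geometry) within
#' 5 percent, which guards against spurious feature consensus.
#'
#' @inheritParams find_overlapping_highmag
#' @param margin_px Extra margin (low-mag pixels) around the stage footprint
#'   when rendering the composite.
#' @return An \code{affine2d} mapping low-mag pixels to world pixels, with
#'   attribute \code{"n_matches"}.
#' @export
register_lowmag_to_montage <- function(emlow_tile, highmag,
                                       world_pixel_size_nm = 5,
                                       margin_px = 8) {
  ov <- find_overlapping_highmag(emlow_tile, highmag, world_pixel_size_nm)
  if (!length(ov))
    stop("cross-spatial registration failed: no overlapping ",
         "high-magnification tiles for '", emlow_tile$tile_id, "'")
  ratio <- emlow_tile$pixel_size_nm / world_pixel_size_nm
  fp <- stage_footprint_world(emlow_tile, world_pixel_size_nm)
  bbox <- c(fp[1] - margin_px * ratio, fp[2] - margin_px * ratio,
            fp[3] + margin_px * ratio, fp[4] + margin_px * ratio)
  comp <- render_composite(ov, bbox, out_pixel_size_nm = emlow_tile$pixel_size_nm,
                           world_pixel_size_nm = world_pixel_size_nm)
  # band-limited coarse imagery carries genuinely lower DoG contrast than
  # native-resolution tiles, so the keypoint threshold is halved here; the
  # RANSAC model is a similarity (the physical low-mag-to-world mapping)
  # whose 2-point minimal sample is far more robust at small match counts
  fl <- tryCatch(extract_features(emlow_tile$image, contrast_thresh = 0.005),
                 error = function(e) empty_feature_set())
  fc <- tryCatch(extract_features(comp, contrast_thresh = 0.005),
                 error = function(e) empty_feature_set())
  m <- match_features(fl, fc, model = "rigid",
                      tile_id_a = emlow_tile$tile_id, tile_id_b = "composite")
  if (nrow(m$pa) < 3L)
    stop("cross-spatial registration failed: ", nrow(m$pa),
         " inlier matches for '", emlow_tile$tile_id, "'")
  fit <- fit_affine(m)   # low-mag px -> composite px
  T_comp_world <- affine_compose(affine_translation(bbox[1], bbox[2]),
                                 affine2d(ratio, 0, 0, ratio, 0, 0))
  T_lw <- affine_compose(T_comp_world, fit)
  sv <- svd(matrix(c(T_lw$a11, T_lw$a12, T_lw$a21, T_lw$a22), 2, byrow = TRUE))$d
  if (any(abs(sv / ratio - 1) > 0.05))
    stop("cross-spatial registration failed: fitted scale ",
         paste(signif(sv, 4), collapse = "/"),
         " deviates more than 5% from the pixel-size ratio ", ratio)
  attr(T_lw, "n_matches") <- nrow(m$pa)
  T_lw
}

#' Assemble an overlay chain
#'
#' @param T_fm_to_emlow Cross-modal transform (from
#'   \code{\link{register_cross_modal}}).
#' @param T_emlow_to_world Cross-spatial transform (from
#'   \code{\link{register_lowmag_to_montage}}).
#' @return Object of class \code{overlay_chain} with the derived
#'   \code{T_fm_to_world}.
#' @export
overlay_chain <- function(T_fm_to_emlow, T_emlow_to_world) {
  stopifnot(inherits(T_fm_to_emlow, "affine2d"),
            inherits(T_emlow_to_world, "affine2d"))
  structure(list(T_fm_to_emlow = T_fm_to_emlow,
                 T_emlow_to_world = T_emlow_to_world,
                 T_fm_to_world = affine_compose(T_emlow_to_world,
                                                T_fm_to_emlow)),
            class = "overlay_chain")
}

#' Overlay an FM tile onto the high-magnification world frame
#'
#' Sets the FM tile's transform to the chained FM-to-world map. When ground
#' truth is supplied (synthetic data), an overlay error report over the FM
#' tile's corner points is attached.
#'
#' @param fm_tile An FM \code{icat_tile}.
#' @param chain An \code{\link{overlay_chain}}.
#' @param truth Optional true FM-to-world \code{affine2d} for error
#'   reporting.
#' @return The FM tile with updated transform; if \code{truth} was given,
#'   attribute \code{"corner_error_world_px"} holds the per-corner mapping
#'   error in world pixels.
#' @export
overlay_fm <- function(fm_tile, chain, truth = NULL) {
  if (!inherits(chain, "overlay_chain") ||
      is.null(chain$T_fm_to_emlow) || is.null(chain$T_emlow_to_world))
    stop("overlay chain is missing a member transform")
  fm_tile$transform <- chain$T_fm_to_world
  if (!is.null(truth)) {
    w <- ncol(fm_tile$image); h <- nrow(fm_tile$image)
    corners <- rbind(c(0, 0), c(w - 1, 0), c(0, h - 1), c(w - 1, h - 1))
    err <- sqrt(rowSums((affine_apply(chain$T_fm_to_world, corners) -
                           affine_apply(truth, corners))^2))
    attr(fm_tile, "corner_error_world_px") <- err
  }
  fm_tile
}
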