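# Tile data model and tile store.
#
# A Tile is one acquired raster (fluorescence, low- or high-magnification EM,
# or the slide overview) with its stage position, pixel size, section index
# and current transform into the section world frame. The world frame per
# section is the high-magnification EM pixel grid (5 nm per pixel), so
# overlays from coarser modalities are expressed at full resolution.
# Images are numeric matrices in [0, 1], rows = y, cols = x, 0-based
# coordinates with pixel centers at integers.

MODALITIES <- c("FM", "EM_LOW", "EM_HIGH", "OVERVIEW")

#' Construct a tile
#'
#' @param tile_id Unique id string within its stack.
#' @param modality One of \code{"FM"}, \code{"EM_LOW"}, \code{"EM_HIGH"},
#'   \code{"OVERVIEW"}.
#' @param image Numeric matrix in \code{[0, 1]} (rows = y).
#' @param section_index Integer z index of the serial section.
#' @param stage_xy Stage position in micrometers, length-2 \code{c(x, y)}.
#' @param pixel_size_nm Pixel size in nm per pixel (5 for EM_HIGH, 38 for
#'   EM_LOW in the reference acquisition geometry).
#' @param transform \code{affine2d} from local pixels into the section world
#'   frame; defaults to identity.
#' @param channel Optional channel name for FM tiles (e.g. "nuclear").
#' @param bit_depth Storage bit depth, 8 or 16.
#' @return An object of class \code{icat_tile}.
#' @export
tile <- function(tile_id, modality, image, section_index = 0L,
                 stage_xy = c(0, 0), pixel_size_nm = 5,
                 transform = affine_identity(), channel = NULL,
                 bit_depth = 8L) {
  stopifnot(is.character(tile_id), length(tile_id) == 1L, nzchar(tile_id))
  modality <- match.arg(modality, MODALITIES)
  if (!is.matrix(image) || length(image) == 0L)
    stop("tile ", tile_id, ": image must be a non-empty matrix")
  if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0)
    stop("tile ", tile_id, ": pixel_size_nm must be positive")
  stopifnot(inherits(transform, "affine2d"), bit_depth %in% c(8L, 16L))
  structure(list(tile_id = tile_id, modality = modality, image = image,
                 section_index = as.integer(section_index),
                 stage_xy = as.numeric(stage_xy),
                 pixel_size_nm = pixel_size_nm, transform = transform,
                 channel = channel, bit_depth = as.integer(bit_depth)),
            class = "icat_tile")
}

#' @export
print.icat_tile <- function(x, ...) {
  cat(sprintf("icat_tile '%s' [%s] z=%d  %dx%d px @ %g nm/px  stage (%g, %g) um\n",
              x$tile_id, x$modality, x$section_index,
              ncol(x$image), nrow(x$image), x$pixel_size_nm,
              x$stage_xy[1], x$stage_xy[2]))
  invisible(x)
}

# World-frame bounding box of a tile under its current transform.
tile_world_bbox <- function(t) {
  w <- ncol(t$image); h <- nrow(t$image)
  corners <- affine_apply(t$transform,
                          rbind(c(0, 0), c(w - 1, 0), c(0, h - 1), c(w - 1, h - 1)))
  c(min(corners[, 1]), min(corners[, 2]), max(corners[, 1]), max(corners[, 2]))
}

#' Create an empty tile store
#'
#' A tile store groups tiles into named stacks (e.g. \code{"fm"},
#' \code{"em_low"}, \code{"em_high"}), each ordered by section index. Section
#' indices need not be contiguous: discarded serial sections simply have no
#' tiles. Metadata records the world pixel size (5 nm) and the section
#' thickness (100 nm) used for z scaling on export.
#'
#' @param world_pixel_size_nm World-frame pixel size in nm.
#' @param section_thickness_nm Physical section thickness in nm.
#' @return An object of class \code{icat_store}.
#' @export
tile_store <- function(world_pixel_size_nm = 5, section_thickness_nm = 100) {
  structure(list(stacks = list(),
                 metadata = list(schema = "icat-spec-1",
                                 world_pixel_size_nm = world_pixel_size_nm,
                                 section_thickness_nm = section_thickness_nm)),
            class = "icat_store")
}

#' Add tiles to a store stack
#' @param store An \code{icat_store}.
#' @param stack Stack name.
#' @param tiles A list of \code{icat_tile} objects.
#' @return The updated store.
#' @export
store_add_tiles <- function(store, stack, tiles) {
  stopifnot(inherits(store, "icat_store"))
  if (inherits(tiles, "icat_tile")) tiles <- list(tiles)
  cur <- store$stacks[[stack]] %||% list()
  ids <- c(vapply(cur, `[[`, "", "tile_id"), vapply(tiles, `[[`, "", "tile_id"))
  if (anyDuplicated(ids))
    stop("duplicate tile_id in stack '", stack, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  store$stacks[[stack]] <- c(cur, tiles)
  store
}

#' Retrieve tiles from a store
#' @param store An \code{icat_store}.
#' @param stack Stack name.
#' @param z Optional section index filter.
#' @return List of \code{icat_tile}.
#' @export
store_tiles <- function(store, stack, z = NULL) {
  tl <- store$stacks[[stack]] %||% list()
  if (!is.null(z)) tl <- Filter(function(t) t$section_index %in% z, tl)
  tl
}

#' Section indices present in a stack
#' @inheritParams store_tiles
#' @return Sorted integer vector.
#' @export
store_sections <- function(store, stack) {
  sort(unique(vapply(store_tiles(store, stack), `[[`, 0L, "section_index")))
}

#' @export
print.icat_store <- function(x, ...) {
  cat("icat_store (schema", x$metadata$schema, ")\n")
  for (nm in names(x$stacks))
    cat(sprintf("  stack '%s': %d tiles, sections %s\n", nm,
                length(x$stacks[[nm]]),
                paste(range(store_sections(x, nm)), collapse = "..")))
  invisible(x)
}

#' Render a composite raster from transformed tiles
#'
#' Samples each output pixel from the last-drawn tile that covers it
#' (painter's order = tile list order) by inverse-transform bilinear
#' interpolation; pixels covered by no tile are 0. Used both to stitch
#' previews and to build the composite that low-magnification tiles are
#' registered against during cross-spatial registration.
#'
#' @param tiles List of \code{icat_tile} with transforms into a common world
#'   frame.
#' @param bbox World-frame rectangle \code{c(xmin, ymin, xmax, ymax)} in world
#'   pixels.
#' @param out_pixel_size_nm Output pixel size; output pixel (i, j) (0-based)
#'   sits at world point \code{bbox[1:2] + (i, j) * scale} with
#'   \code{scale = out_pixel_size_nm / world_pixel_size_nm}.
#' @param world_pixel_size_nm World pixel size in nm (default 5).
#' @return Numeric matrix (rows = y) covering the bbox at the requested scale.
#' @export
render_composite <- function(tiles, bbox, out_pixel_size_nm,
                             world_pixel_size_nm = 5) {
  stopifnot(length(bbox) == 4L, bbox[3] >= bbox[1], bbox[4] >= bbox[2])
  hit <- vapply(tiles, function(t) box_intersects(tile_world_bbox(t), bbox), NA)
  if (!any(hit))
    stop("no tile intersects bbox [", paste(signif(bbox, 6), collapse = ", "), "]")
  s <- out_pixel_size_nm / world_pixel_size_nm
  nx <- floor((bbox[3] - bbox[1]) / s + 1e-9) + 1L
  ny <- floor((bbox[4] - bbox[2]) / s + 1e-9) + 1L
  wx <- bbox[1] + (seq_len(nx) - 1L) * s
  wy <- bbox[2] + (seq_len(ny) - 1L) * s
  X <- matrix(wx, nrow = ny, ncol = nx, byrow = TRUE)
  Y <- matrix(wy, nrow = ny, ncol = nx)
  out <- matrix(0, ny, nx)
  for (t in tiles[hit]) {
    inv <- affine_invert(t$transform)
    # anti-alias: when the output grid is much coarser than the tile,
    # low-pass the tile at half the sampling period before point sampling
    tile_scale <- sqrt(abs(affine_det(t$transform)))
    rel <- s / max(tile_scale, 1e-12)
    if (rel > 1.5) t$image <- gauss_blur(t$image, 0.5 * rel)
    loc <- affine_apply(inv, cbind(as.vector(X), as.vector(Y)))
    lx <- loc[, 1]; ly <- loc[, 2]
    inside <- lx >= 0 & ly >= 0 & lx <= ncol(t$image) - 1 & ly <= nrow(t$image) - 1
    if (!any(inside)) next
    v <- sample_bilinear(t$image, lx[inside], ly[inside])
    out[inside] <- v
  }
  out
}
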