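# Tile store persistence: single-plane grayscale TIFF images plus a JSON
# tile-spec file ("icat-spec-1" dialect). One JSON record per tile: id,
# modality, z, stage position (um), pixel size (nm), the 6 transform
# coefficients row-major [a11, a12, tx, a21, a22, ty], and the image path
# relative to the store root. PNG images are accepted on read.

#' Write a tile store to disk
#'
#' Images are written as single-plane grayscale TIFF at each tile's bit
#' depth under \code{tiles/}; metadata goes to \code{tilespecs.json}. A
#' write/read round trip preserves every field (images are quantized to the
#' tile's bit depth on the first write and exact thereafter).
#'
#' @param store An \code{icat_store}.
#' @param path Directory to create/overwrite.
#' @return \code{path}, invisibly.
#' @export
write_store <- function(store, path) {
  stopifnot(inherits(store, "icat_store"))
  dir.create(file.path(path, "tiles"), recursive = TRUE, showWarnings = FALSE)
  spec <- list(schema = store$metadata$schema,
               metadata = store$metadata[setdiff(names(store$metadata), "schema")],
               stacks = list())
  for (nm in names(store$stacks)) {
    recs <- lapply(store$stacks[[nm]], function(t) {
      img_rel <- file.path("tiles", paste0(nm, "_", t$tile_id, ".tif"))
      tiff::writeTIFF(pmin(pmax(t$image, 0), 1), file.path(path, img_rel),
                      bits.per.sample = t$bit_depth)
      rec <- list(id = t$tile_id, modality = t$modality, z = t$section_index,
                  stage_xy_um = t$stage_xy, pixel_size_nm = t$pixel_size_nm,
                  transform = affine_coefs(t$transform), image = img_rel,
                  bit_depth = t$bit_depth)
      if (!is.null(t$channel)) rec$channel <- t$channel
      rec
    })
    spec$stacks[[nm]] <- recs
  }
  jsonlite::write_json(spec, file.path(path, "tilespecs.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

read_image_file <- function(f) {
  ext <- tolower(tools::file_ext(f))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(f),
                png = png::readPNG(f),
                stop("unsupported image format: ", f))
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # grayscale plane
  img
}

#' Read a tile store from disk
#'
#' @param path Store directory written by \code{\link{write_store}}.
#' @return An \code{icat_store}.
#' @export
read_store <- function(path) {
  specf <- file.path(path, "tilespecs.json")
  if (!file.exists(specf)) stop("not a tile store (missing tilespecs.json): ", path)
  spec <- jsonlite::read_json(specf)
  md <- spec$metadata
  store <- tile_store(world_pixel_size_nm = md$world_pixel_size_nm %||% 5,
                      section_thickness_nm = md$section_thickness_nm %||% 100)
  store$metadata$schema <- spec$schema %||% "icat-spec-1"
  for (nm in names(spec$stacks)) {
    tiles <- lapply(spec$stacks[[nm]], function(rec) {
      id <- rec$id %||% "<missing id>"
      tr <- unlist(rec$transform)
      if (length(tr) != 6L)
        stop("malformed record for tile '", id, "': expected 6 transform ",
             "coefficients, got ", length(tr))
      imgf <- file.path(path, rec$image)
      if (!file.exists(imgf))
        stop("missing image file for tile '", id, "': ", imgf)
      tile(tile_id = id, modality = rec$modality,
           image = read_image_file(imgf),
           section_index = rec$z, stage_xy = unlist(rec$stage_xy_um),
           pixel_size_nm = rec$pixel_size_nm,
           transform = affine_from_coefs(tr),
           channel = rec$channel,
           bit_depth = rec$bit_depth %||% 8L)
    })
    store <- store_add_tiles(store, nm, tiles)
  }
  store
}
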