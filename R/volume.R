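# Serial-section volume alignment.
#
# Rough z alignment registers a downsampled render of each section to its
# nearest preceding present section (full-resolution montages are far too
# large for feature extraction). Fine alignment then solves one sparse
# least-squares system over all tiles of all sections, combining the
# intra-section (montage) matches with cross-section matches gathered under
# a depth-search plan. The depth-search window d is the maximum z
# separation considered when matching features across sections; raising it
# bridges discarded sections (two consecutive missing sections require
# d >= 3, e.g. matching z = 8 directly to z = 11).

#' Build a feature depth-search plan
#'
#' Lists the section pairs (za, zb), za < zb, with 0 < zb - za <= depth and
#' both sections present, and reports whether the resulting section graph
#' is connected. A disconnected graph means the fine alignment cannot bridge
#' a gap of discarded sections at this depth.
#'
#' @param present_z Integer vector of present section indices (gaps
#'   allowed).
#' @param depth Depth-search window d >= 1.
#' @return Object of class \code{depth_search_plan}: \code{present_z},
#'   \code{depth}, \code{pairs} (m-by-2 matrix, za < zb), \code{connected},
#'   \code{components} (list of section groups).
#' @export
build_depth_plan <- function(present_z, depth) {
  stopifnot(depth >= 1)
  present_z <- sort(unique(as.integer(present_z)))
  prs <- list()
  for (i in seq_along(present_z)) {
    za <- present_z[i]
    zb <- present_z[present_z > za & present_z <= za + depth]
    if (length(zb)) prs[[length(prs) + 1L]] <- cbind(za, zb)
  }
  pairs <- if (length(prs)) do.call(rbind, prs) else
    matrix(integer(0), 0, 2)
  colnames(pairs) <- c("za", "zb")
  # union-find connectivity over present sections
  parent <- seq_along(present_z)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    a <- find(match(pairs[k, 1], present_z)); b <- find(match(pairs[k, 2], present_z))
    if (a != b) parent[a] <- b
  }
  comps <- split(present_z, vapply(seq_along(present_z), find, 0L))
  structure(list(present_z = present_z, depth = depth, pairs = pairs,
                 connected = length(comps) <= 1L,
                 components = unname(comps)),
            class = "depth_search_plan")
}

#' @export
print.depth_search_plan <- function(x, ...) {
  cat(sprintf("depth_search_plan: %d sections, depth %d, %d pairs, %s\n",
              length(x$present_z), x$depth, nrow(x$pairs),
              if (x$connected) "connected" else
                paste0(length(x$components), " components")))
  invisible(x)
}

#' Minimal depth-search window restoring connectivity
#'
#' Increases the depth from 1 until \code{\link{build_depth_plan}} declares
#' the section graph connected; this is the automatic counterpart of
#' manually raising the window when consecutive sections were discarded.
#'
#' @param present_z Present section indices.
#' @param max_depth Upper bound on the search.
#' @return The smallest connecting depth, or NA if none up to
#'   \code{max_depth}.
#' @export
min_connecting_depth <- function(present_z, max_depth = 16L) {
  for (d in seq_len(max_depth))
    if (build_depth_plan(present_z, d)$connected) return(d)
  NA_integer_
}

#' Rough per-section z alignment on downsampled renders
#'
#' The first present section is fixed to identity; each subsequent present
#' section is registered to its nearest preceding present section by
#' feature matching and an affine fit at the downsampled scale, then the
#' pairwise transforms are chained and rescaled to full resolution.
#'
#' @param sections Named list of section rasters (names \code{"z<k>"}),
#'   full-resolution stitched renders in z order.
#' @param downsample_factor Integer downsampling factor (default 16 for
#'   multi-gigabyte montages; tests use smaller renders and factors).
#' @return Named list of full-resolution \code{affine2d} mapping each
#'   section's pixels into the first present section's frame.
#' @export
rough_align_z <- function(sections, downsample_factor = 16L) {
  stopifnot(length(sections) >= 1L)
  zs <- as.integer(sub("^z", "", names(sections)))
  ord <- order(zs)
  sections <- sections[ord]; zs <- zs[ord]
  S <- affine2d(downsample_factor, 0, 0, downsample_factor, 0, 0)
  Sinv <- affine_invert(S)
  out <- stats::setNames(vector("list", length(zs)), names(sections))
  out[[1L]] <- affine_identity()
  if (length(zs) == 1L) return(out)
  feats <- vector("list", length(zs))
  ds <- lapply(sections, downsample_mean, factor = downsample_factor)
  feats[[1L]] <- extract_features(ds[[1L]])
  for (i in 2L:length(zs)) {
    feats[[i]] <- extract_features(ds[[i]])
    m <- match_features(feats[[i]], feats[[i - 1L]], model = "affine")
    if (nrow(m$pa) < 3L)
      stop("no matches between sections z=", zs[i - 1L], " and z=", zs[i],
           " during rough alignment")
    T_ds <- fit_affine(m)                    # this section -> previous, downsampled
    T_full <- affine_compose(S, affine_compose(T_ds, Sinv))
    out[[i]] <- affine_compose(out[[i - 1L]], T_full)
  }
  out
}

#' Cross-section feature matches under a depth plan
#'
#' For every section pair in the plan, features of the tiles of the two
#' sections (cached per tile, reusing the stitching features) are matched
#' and RANSAC-filtered; only tile pairs whose rough-aligned footprints lie
#' within twice the tile field of each other are attempted. Matches are
#' expressed in tile-local frames and weighted by \code{inter_weight}.
#'
#' @param tiles_by_z Named list ("z<k>") of per-section tile lists; each
#'   tile's transform must be its rough-aligned world initialization.
#' @param plan A \code{\link{depth_search_plan}}.
#' @param features Optional named cache of \code{feature_set} per tile id;
#'   computed (and cached) from tile images when absent.
#' @param inter_weight Weight for cross-section pairs (default 0.5).
#' @return List of \code{point_match_set} (possibly empty sets omitted).
#' @export
cross_section_matches <- function(tiles_by_z, plan, features = NULL,
                                  inter_weight = 0.5) {
  features <- features %||% list()
  getf <- function(t) {
    f <- features[[t$tile_id]]
    if (is.null(f)) {
      f <- tryCatch(extract_features(t$image),
                    error = function(e) empty_feature_set())
      features[[t$tile_id]] <<- f
    }
    f
  }
  out <- list()
  for (k in seq_len(nrow(plan$pairs))) {
    za <- plan$pairs[k, 1]; zb <- plan$pairs[k, 2]
    ta <- tiles_by_z[[paste0("z", za)]]; tb <- tiles_by_z[[paste0("z", zb)]]
    if (is.null(ta) || is.null(tb)) next
    for (a in ta) for (b in tb) {
      fa_box <- tile_world_bbox(a); fb_box <- tile_world_bbox(b)
      field <- max(fa_box[3] - fa_box[1], fa_box[4] - fa_box[2])
      ca <- c(mean(fa_box[c(1, 3)]), mean(fa_box[c(2, 4)]))
      cb <- c(mean(fb_box[c(1, 3)]), mean(fb_box[c(2, 4)]))
      if (sqrt(sum((ca - cb)^2)) > 2 * field) next
      m <- match_features(getf(a), getf(b), model = "affine",
                          tile_id_a = a$tile_id, tile_id_b = b$tile_id)
      if (nrow(m$pa) > 0L) {
        m$weights <- rep(inter_weight, nrow(m$pa))
        out[[length(out) + 1L]] <- m
      }
    }
  }
  out
}

#' Fine 3D alignment of the serial-section stack
#'
#' One sparse least-squares solve over all tiles of all present sections,
#' combining intra-section (montage) and cross-section matches, with
#' regularization toward each tile's initialization (montage solution
#' composed with the rough z transform) and the first present section's
#' anchor tile fixing the gauge. A disconnected combined match graph is an
#' error naming the weakly connected section groups — the mitigation is to
#' raise the depth-search window.
#'
#' @param tiles Flat list of \code{icat_tile} across sections; each tile's
#'   transform is its initialization.
#' @param intra List of intra-section \code{point_match_set}.
#' @param inter List of cross-section \code{point_match_set} (from
#'   \code{\link{cross_section_matches}}).
#' @param opts A \code{\link{solver_options}}.
#' @return Named list of solved \code{affine2d} per tile id (attribute
#'   \code{"residual_rms"} as in \code{\link{solve_montage}}).
#' @export
solve_volume <- function(tiles, intra, inter, opts = solver_options()) {
  ids <- vapply(tiles, `[[`, "", "tile_id")
  zs <- vapply(tiles, `[[`, 0L, "section_index")
  comps <- match_components(ids, c(intra, inter))
  if (length(comps) > 1L) {
    groups <- vapply(comps, function(cc) {
      gz <- sort(unique(zs[ids %in% cc]))
      paste0("z=", paste(gz, collapse = ","))
    }, "")
    stop("disconnected across sections: groups {",
         paste(groups, collapse = "} {"),
         "}; raise the depth-search window to bridge the gap")
  }
  if (is.null(opts$anchor)) {
    z0 <- min(zs)
    opts$anchor <- sort(ids[zs == z0])[1L]
  }
  solve_correspondences(tiles, c(intra, inter), opts)
}

#' Export aligned sections as a z stack
#'
#' Renders every present section into a common world-frame bounding box and
#' stacks the planes in z order. The z spacing metadata is the section
#' thickness (100 nm).
#'
#' @param sections_by_z Named list ("z<k>") of per-section tile lists with
#'   solved transforms (a bare raster matrix is accepted and wrapped).
#' @param bbox World bbox to render; default: union of tile footprints.
#' @param out_pixel_size_nm Output pixel size.
#' @param world_pixel_size_nm World pixel size.
#' @param path Optional file path; when given the stack is written as a
#'   multi-plane TIFF.
#' @return 3D array (y, x, z) with attribute \code{"z_indices"} and
#'   \code{"z_spacing_nm"} = 100.
#' @export
export_stack <- function(sections_by_z, bbox = NULL, out_pixel_size_nm = 5,
                         world_pixel_size_nm = 5, path = NULL) {
  zs <- sort(as.integer(sub("^z", "", names(sections_by_z))))
  tl <- lapply(paste0("z", zs), function(k) {
    s <- sections_by_z[[k]]
    if (is.matrix(s)) s <- list(tile(paste0("sec_", k), "EM_HIGH", s))
    s
  })
  if (is.null(bbox)) {
    bbs <- do.call(rbind, lapply(unlist(tl, recursive = FALSE),
                                 tile_world_bbox))
    bbox <- c(min(bbs[, 1]), min(bbs[, 2]), max(bbs[, 3]), max(bbs[, 4]))
  }
  planes <- lapply(tl, render_composite, bbox = bbox,
                   out_pixel_size_nm = out_pixel_size_nm,
                   world_pixel_size_nm = world_pixel_size_nm)
  arr <- array(unlist(planes), dim = c(dim(planes[[1L]]), length(planes)))
  attr(arr, "z_indices") <- zs
  attr(arr, "z_spacing_nm") <- 100
  if (!is.null(path))
    tiff::writeTIFF(planes, path, bits.per.sample = 8L)
  arr
}
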