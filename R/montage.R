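# Acquisition-grid planning and per-section montage stitching.
#
# The correlative acquisition alternates FM and low-magnification EM tiles
# on a grid covering each section; the EM field width is trimmed so it never
# enters the overlap band of neighboring FM tiles (w_EM = w_FM - 2 o w_FM).
# High-magnification tiles over the fluorescence-selected ROI are stitched
# by minimizing the squared distance between matched features across all
# neighboring tile pairs in one sparse regularized least-squares system,
# with the anchor tile pinned to its stage-derived transform (gauge fixing).

#' EM field width compatible with the FM overlap
#'
#' The EM tile must span the largest field that stays clear of the
#' neighboring FM tiles' overlap bands (which must remain undamaged by the
#' beam for stitching and ROI detection):
#' \code{w_em = w_fm - 2 * o_fm * w_fm}.
#'
#' @param w_fm FM field width (micrometers).
#' @param o_fm FM overlap fraction in [0, 0.5).
#' @return EM field width in micrometers.
#' @export
em_field_width <- function(w_fm, o_fm) {
  if (o_fm < 0) stop("overlap fraction must be >= 0")
  if (o_fm >= 0.5) stop("no EM field remains: overlap fraction >= 0.5")
  w_fm * (1 - 2 * o_fm)
}

#' Plan a serpentine acquisition grid over a section
#'
#' Field centers on a row-major serpentine grid with pitch
#' \code{w_fm * (1 - o_fm)}, covering the section bounding box (the union of
#' FM fields is a superset of the box). A box smaller than one field yields
#' a single centered position.
#'
#' @param section_box Stage-frame box c(xmin, ymin, xmax, ymax) in um.
#' @param w_fm FM field width in um.
#' @param o_fm FM overlap fraction.
#' @return Data frame with columns x, y (field centers, um), row, col, in
#'   serpentine acquisition order.
#' @export
plan_acquisition_grid <- function(section_box, w_fm, o_fm) {
  stopifnot(length(section_box) == 4L,
            section_box[3] >= section_box[1], section_box[4] >= section_box[2])
  pitch <- w_fm * (1 - o_fm)
  W <- section_box[3] - section_box[1]; H <- section_box[4] - section_box[2]
  nx <- max(1L, ceiling(W / pitch)); ny <- max(1L, ceiling(H / pitch))
  cx <- if (nx == 1L) mean(section_box[c(1, 3)]) else
    section_box[1] + w_fm / 2 + (seq_len(nx) - 1L) * pitch
  cy <- if (ny == 1L) mean(section_box[c(2, 4)]) else
    section_box[2] + w_fm / 2 + (seq_len(ny) - 1L) * pitch
  out <- do.call(rbind, lapply(seq_len(ny), function(r) {
    cols <- if (r %% 2L == 1L) seq_len(nx) else rev(seq_len(nx))
    data.frame(x = cx[cols], y = cy[r], row = r - 1L, col = cols - 1L)
  }))
  rownames(out) <- NULL
  out
}

#' Candidate neighboring tile pairs from stage coordinates
#'
#' Pairs of same-modality tiles whose nominal stage footprints (stage
#' position extended by the field size) overlap after dilating each
#' footprint by 10 percent of the field width. Feature matching is only
#' attempted between candidate neighbors.
#'
#' @param tiles List of \code{icat_tile} sharing modality and pixel size;
#'   \code{stage_xy} is the stage position (um) of the tile's local origin.
#' @return Data frame with columns \code{a}, \code{b} (tile ids,
#'   \code{a < b} lexicographically); zero rows when no footprints touch.
#' @export
candidate_neighbors <- function(tiles) {
  n <- length(tiles)
  if (n < 2L)
    return(data.frame(a = character(0), b = character(0)))
  mods <- vapply(tiles, `[[`, "", "modality")
  if (length(unique(mods)) != 1L)
    stop("candidate_neighbors requires tiles of a single modality")
  boxes <- lapply(tiles, function(t) {
    fw <- ncol(t$image) * t$pixel_size_nm / 1000
    fh <- nrow(t$image) * t$pixel_size_nm / 1000
    d <- 0.1 * max(fw, fh) / 2
    c(t$stage_xy[1] - d, t$stage_xy[2] - d,
      t$stage_xy[1] + fw + d, t$stage_xy[2] + fh + d)
  })
  ids <- vapply(tiles, `[[`, "", "tile_id")
  out <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    if (box_intersects(boxes[[i]], boxes[[j]])) {
      pr <- sort(c(ids[i], ids[j]))
      out[[length(out) + 1L]] <- data.frame(a = pr[1], b = pr[2])
    }
  if (!length(out)) return(data.frame(a = character(0), b = character(0)))
  do.call(rbind, out)
}

#' Solver options for montage and volume alignment
#'
#' @param model Per-tile transform model: \code{"translation"} (the default
#'   for stage-driven montages), \code{"rigid"} (similarity) or
#'   \code{"affine"}.
#' @param lambda Regularization weight pulling each tile toward its
#'   stage-derived initial transform; removes drift of weakly constrained
#'   tiles without fighting the data term.
#' @param anchor Tile id fixed to its initial transform (gauge fixing);
#'   default: lexicographically smallest tile id.
#' @param inter_weight Relative weight of cross-section matches in the 3D
#'   solve.
#' @return List of class \code{solver_options}.
#' @export
solver_options <- function(model = c("translation", "rigid", "affine"),
                           lambda = 0.005, anchor = NULL, inter_weight = 0.5) {
  model <- match.arg(model)
  stopifnot(lambda >= 0, inter_weight >= 0)
  structure(list(model = model, lambda = lambda, anchor = anchor,
                 inter_weight = inter_weight), class = "solver_options")
}

# ---- sparse correspondence solver ------------------------------------------
# Shared by solve_montage (2D) and solve_volume (3D). Unknowns per tile:
#   translation: (tx, ty), linear part frozen at the initial transform;
#   rigid:       (a, b, tx, ty) with A = [a -b; b a];
#   affine:      (a11, a12, a21, a22, tx, ty).
# Data rows: for each match pair, T_a(p) - T_b(q) = 0 (x and y rows).
# Regularization rows: sqrt(lambda) * (theta - theta_init) for every unknown.
# The anchor tile's parameters are eliminated (fixed at its initial
# transform), which fixes the global gauge.

n_par <- function(model) switch(model, translation = 2L, rigid = 4L, affine = 6L)

# Per-tile parameter vector from an affine2d under the given model.
par_from_transform <- function(T, model) {
  switch(model,
         translation = c(T$tx, T$ty),
         rigid = c(T$a11, T$a21, T$tx, T$ty),
         affine = c(T$a11, T$a12, T$a21, T$a22, T$tx, T$ty))
}

transform_from_par <- function(theta, model, init) {
  switch(model,
         translation = affine2d(init$a11, init$a12, init$a21, init$a22,
                                theta[1], theta[2]),
         rigid = affine2d(theta[1], -theta[2], theta[2], theta[1],
                          theta[3], theta[4]),
         affine = affine2d(theta[1], theta[2], theta[3], theta[4],
                           theta[5], theta[6]))
}

# Coefficient rows for T(p) under the model: returns list(x=..., y=...) of
# coefficient vectors over the tile's parameters, plus constant offsets.
point_rows <- function(p, model, init) {
  x <- p[, 1]; y <- p[, 2]; n <- length(x); one <- rep(1, n); zero <- rep(0, n)
  switch(model,
         translation = list(
           Ax = cbind(one, zero), Ay = cbind(zero, one),
           cx = init$a11 * x + init$a12 * y, cy = init$a21 * x + init$a22 * y),
         rigid = list(
           Ax = cbind(x, -y, one, zero), Ay = cbind(y, x, zero, one),
           cx = zero, cy = zero),
         affine = list(
           Ax = cbind(x, y, zero, zero, one, zero),
           Ay = cbind(zero, zero, x, y, zero, one),
           cx = zero, cy = zero))
}

# Connected components of the tile graph induced by non-empty match sets.
match_components <- function(ids, matches) {
  parent <- seq_along(ids); names(parent) <- ids
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (m in matches) {
    if (nrow(m$pa) == 0L) next
    if (!(m$tile_id_a %in% ids) || !(m$tile_id_b %in% ids)) next
    ra <- find(which(ids == m$tile_id_a)); rb <- find(which(ids == m$tile_id_b))
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_along(ids), find, 0L)
  split(ids, roots)
}

solve_correspondences <- function(tiles, matches, opts) {
  ids <- vapply(tiles, `[[`, "", "tile_id")
  stopifnot(!anyDuplicated(ids))
  comps <- match_components(ids, matches)
  if (length(comps) > 1L)
    stop("disconnected match graph: components {",
         paste(vapply(comps, function(cc) paste(cc, collapse = ","), ""),
               collapse = "} {"), "}")
  model <- opts$model
  np <- n_par(model)
  anchor <- opts$anchor %||% sort(ids)[1L]
  if (!(anchor %in% ids)) stop("anchor tile '", anchor, "' not in tile list")
  init <- lapply(tiles, `[[`, "transform"); names(init) <- ids
  free <- setdiff(ids, anchor)
  col_of <- stats::setNames(seq_along(free), free)
  ncol_tot <- length(free) * np
  trip_i <- list(); trip_j <- list(); trip_x <- list(); rhs <- list()
  row0 <- 0L
  add_rows <- function(cols, vals, b) {
    k <- length(trip_i) + 1L
    trip_i[[k]] <<- rep(row0 + seq_len(nrow(vals)), ncol(vals))
    trip_j[[k]] <<- rep(cols, each = nrow(vals))
    trip_x[[k]] <<- as.vector(vals)
    rhs[[k]] <<- b
    row0 <<- row0 + nrow(vals)
  }
  anchor_T <- init[[anchor]]
  for (m in matches) {
    n <- nrow(m$pa)
    if (n == 0L) next
    a <- m$tile_id_a; b <- m$tile_id_b
    sw <- sqrt(m$weights)
    ra <- point_rows(m$pa, model, init[[a]])
    rb <- point_rows(m$pb, model, init[[b]])
    for (axis in c("x", "y")) {
      Aa <- if (axis == "x") ra$Ax else ra$Ay
      Ab <- if (axis == "x") rb$Ax else rb$Ay
      ca <- if (axis == "x") ra$cx else ra$cy
      cb <- if (axis == "x") rb$cx else rb$cy
      bvec <- (cb - ca) * sw
      blocks <- list(); cols <- integer(0)
      if (a != anchor) { blocks <- c(blocks, list(Aa * sw)); cols <- c(cols, (col_of[a] - 1L) * np + seq_len(np)) }
      else bvec <- bvec - as.vector(Aa %*% par_from_transform(anchor_T, model)) * sw
      if (b != anchor) { blocks <- c(blocks, list(-Ab * sw)); cols <- c(cols, (col_of[b] - 1L) * np + seq_len(np)) }
      else bvec <- bvec + as.vector(Ab %*% par_from_transform(anchor_T, model)) * sw
      if (length(blocks))
        add_rows(cols, do.call(cbind, blocks), bvec)
    }
  }
  # regularization toward the stage-derived initial transforms
  if (opts$lambda > 0 && length(free)) {
    sl <- sqrt(opts$lambda)
    for (id in free) {
      cols <- (col_of[id] - 1L) * np + seq_len(np)
      add_rows(cols, diag(sl, np), sl * par_from_transform(init[[id]], model))
    }
  }
  out <- stats::setNames(vector("list", length(ids)), ids)
  out[[anchor]] <- anchor_T
  if (length(free)) {
    if (row0 == 0L)
      stop("underdetermined system: no matches and lambda = 0")
    A <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                              x = unlist(trip_x), dims = c(row0, ncol_tot))
    b <- unlist(rhs)
    AtA <- Matrix::forceSymmetric(Matrix::crossprod(A))
    theta <- tryCatch(as.vector(Matrix::solve(AtA, Matrix::crossprod(A, b))),
                      error = function(e)
                        stop("rank-deficient alignment system: ",
                             conditionMessage(e)))
    for (id in free) {
      th <- theta[(col_of[id] - 1L) * np + seq_len(np)]
      out[[id]] <- transform_from_par(th, model, init[[id]])
    }
  }
  rms <- vapply(matches, function(m) {
    if (nrow(m$pa) == 0L) return(NA_real_)
    d <- affine_apply(out[[m$tile_id_a]], m$pa) -
         affine_apply(out[[m$tile_id_b]], m$pb)
    sqrt(mean(rowSums(d^2)))
  }, 0)
  attr(out, "residual_rms") <- rms
  out
}

#' Solve a per-section montage
#'
#' Estimates one transform per tile minimizing the total squared distance
#' between matched features across all tile pairs, plus a regularization
#' term \code{lambda * ||T - T_stage||^2} pulling each tile toward its
#' stage-derived initial transform, with the anchor tile fixed (gauge). The
#' whole montage is one sparse linear least-squares solve.
#'
#' @param tiles List of \code{icat_tile}; each tile's current transform is
#'   its stage-derived initialization.
#' @param matches List of \code{point_match_set} between tile pairs.
#' @param opts A \code{\link{solver_options}}.
#' @return Named list of solved \code{affine2d} per tile id, with attribute
#'   \code{"residual_rms"} (per-match-set RMS residual in world pixels).
#' @export
solve_montage <- function(tiles, matches, opts = solver_options()) {
  solve_correspondences(tiles, matches, opts)
}
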