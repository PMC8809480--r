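# Scale-invariant local features for EM tile stitching and serial-section
# alignment: difference-of-Gaussian keypoints with gradient-orientation
# histogram descriptors (4x4 spatial bins x 8 orientations, 128-d), matched
# by a descriptor ratio test and filtered by RANSAC under the montage
# transform model. Deterministic given identical input.

# Weighted bin count: sum of w by integer bin in 1..n (C-backed rowsum).
wt_bincount <- function(bin, w, n) {
  out <- numeric(n)
  rs <- rowsum(w, bin)
  out[as.integer(rownames(rs))] <- rs[, 1L]
  out
}

# 3x3 neighborhood max/min via shifted copies (border replicated).
shift_mat <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) + dy, 1L), h)
  ci <- pmin(pmax(seq_len(w) + dx, 1L), w)
  m[ri, ci, drop = FALSE]
}
neigh_extreme <- function(m, fun) {
  out <- m
  for (dy in -1:1) for (dx in -1:1)
    if (dy != 0L || dx != 0L) out <- fun(out, shift_mat(m, dy, dx))
  out
}

gauss_blur <- function(img, sigma) {
  if (sigma < 0.25) return(img)
  # kernel must fit inside the image; clamp for very small rasters
  r <- min(max(1L, ceiling(3 * sigma)), (min(dim(img)) - 1L) %/% 2L)
  if (r < 1L) return(img)
  k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
  # separable convolution with replicated borders via padded filter2
  kx <- matrix(k, nrow = 1L); ky <- matrix(k, ncol = 1L)
  img <- EBImage::filter2(img, ky, boundary = "replicate")
  EBImage::filter2(img, kx, boundary = "replicate")
}

#' Extract scale-invariant keypoints and descriptors
#'
#' Builds a Gaussian scale-space pyramid, detects extrema of the
#' difference-of-Gaussian response across space and scale, rejects
#' low-contrast and edge-like responses, refines positions to sub-pixel
#' precision, assigns a dominant gradient orientation, and computes a 128-d
#' gradient-orientation histogram descriptor per keypoint. Featureless
#' (e.g. constant) images yield an empty set.
#'
#' @param image Numeric matrix in \code{[0, 1]}, at least 64x64.
#' @param n_max Keep at most this many keypoints (strongest response first).
#' @param contrast_thresh Minimum absolute DoG response (image units).
#' @param edge_ratio Maximum principal-curvature ratio (Harris-style edge
#'   rejection); 10 keeps blob-like responses only.
#' @return An object of class \code{feature_set}: \code{keypoints} (n-by-2,
#'   sub-pixel x/y in image pixels), \code{scale}, \code{orientation}
#'   (radians), \code{response}, and \code{descriptors} (n-by-128, L2
#'   normalized).
#' @export
extract_features <- function(image, n_max = 1000L, contrast_thresh = 0.01,
                             edge_ratio = 10) {
  stopifnot(is.matrix(image))
  if (min(dim(image)) < 64L)
    stop("image too small for feature extraction (need >= 64x64)")
  s <- 3L                      # scales per octave
  sigma0 <- 1.6
  n_oct <- max(1L, floor(log2(min(dim(image)) / 16)))
  kps <- list()
  base <- gauss_blur(image, sqrt(max(sigma0^2 - 0.25, 0.01)))
  for (oct in seq_len(n_oct) - 1L) {
    h <- nrow(base); w <- ncol(base)
    sigmas <- sigma0 * 2^((0:(s + 2L)) / s)
    G <- vector("list", s + 3L)
    G[[1L]] <- base
    for (k in 2L:(s + 3L)) {
      dsig <- sqrt(sigmas[k]^2 - sigmas[k - 1L]^2)
      G[[k]] <- gauss_blur(G[[k - 1L]], dsig)
    }
    D <- lapply(1L:(s + 2L), function(k) G[[k + 1L]] - G[[k]])
    for (k in 2L:(s + 1L)) {
      d <- D[[k]]
      mx <- pmax(neigh_extreme(D[[k - 1L]], pmax),
                 neigh_extreme(d, pmax), neigh_extreme(D[[k + 1L]], pmax),
                 D[[k - 1L]], D[[k + 1L]])
      mn <- pmin(neigh_extreme(D[[k - 1L]], pmin),
                 neigh_extreme(d, pmin), neigh_extreme(D[[k + 1L]], pmin),
                 D[[k - 1L]], D[[k + 1L]])
      is_ext <- (d >= mx | d <= mn) & abs(d) > 0.8 * contrast_thresh
      is_ext[c(1L, h), ] <- FALSE; is_ext[, c(1L, w)] <- FALSE
      idx <- which(is_ext)
      if (!length(idx)) next
      iy <- ((idx - 1L) %% h) + 1L
      ix <- ((idx - 1L) %/% h) + 1L
      # Hessian edge test + 2D quadratic sub-pixel refinement
      dxx <- d[cbind(iy, ix + 1L)] + d[cbind(iy, ix - 1L)] - 2 * d[idx]
      dyy <- d[cbind(iy + 1L, ix)] + d[cbind(iy - 1L, ix)] - 2 * d[idx]
      dxy <- (d[cbind(iy + 1L, ix + 1L)] - d[cbind(iy + 1L, ix - 1L)] -
              d[cbind(iy - 1L, ix + 1L)] + d[cbind(iy - 1L, ix - 1L)]) / 4
      tr <- dxx + dyy; det <- dxx * dyy - dxy^2
      ok <- det > 0 & tr^2 / det < (edge_ratio + 1)^2 / edge_ratio
      if (!any(ok)) next
      iy <- iy[ok]; ix <- ix[ok]; idx <- idx[ok]
      dxx <- dxx[ok]; dyy <- dyy[ok]; dxy <- dxy[ok]
      gx <- (d[cbind(iy, ix + 1L)] - d[cbind(iy, ix - 1L)]) / 2
      gy <- (d[cbind(iy + 1L, ix)] - d[cbind(iy - 1L, ix)]) / 2
      det <- dxx * dyy - dxy^2
      offx <- ifelse(abs(det) > 1e-12, -( dyy * gx - dxy * gy) / det, 0)
      offy <- ifelse(abs(det) > 1e-12, -(-dxy * gx + dxx * gy) / det, 0)
      offx <- pmin(pmax(offx, -0.5), 0.5); offy <- pmin(pmax(offy, -0.5), 0.5)
      resp <- d[idx] + 0.5 * (gx * offx + gy * offy)
      keep <- abs(resp) > contrast_thresh
      if (!any(keep)) next
      kp <- data.frame(x = (ix[keep] - 1 + offx[keep]),
                       y = (iy[keep] - 1 + offy[keep]),
                       level = k, octave = oct, response = abs(resp[keep]),
                       sigma_oct = sigmas[k])
      kp$gimg <- k  # Gaussian level index used for orientation/descriptor
      kps[[length(kps) + 1L]] <- describe_keypoints(kp, G[[k]])
    }
    if (oct < n_oct - 1L) {
      nb <- G[[s + 1L]]
      base <- nb[seq(1L, nrow(nb), by = 2L), seq(1L, ncol(nb), by = 2L), drop = FALSE]
      if (min(dim(base)) < 16L) break
    }
  }
  if (!length(kps)) return(empty_feature_set())
  all <- do.call(rbind, lapply(kps, `[[`, "kp"))
  desc <- do.call(rbind, lapply(kps, `[[`, "desc"))
  if (!nrow(all)) return(empty_feature_set())
  ord <- order(-all$response)
  if (length(ord) > n_max) ord <- ord[seq_len(n_max)]
  all <- all[ord, , drop = FALSE]; desc <- desc[ord, , drop = FALSE]
  fac <- 2^all$octave
  structure(list(keypoints = cbind(x = all$x * fac, y = all$y * fac),
                 scale = all$sigma_oct * fac,
                 orientation = all$orientation,
                 response = all$response,
                 descriptors = desc),
            class = "feature_set")
}

empty_feature_set <- function() {
  structure(list(keypoints = matrix(numeric(0), 0L, 2L,
                                    dimnames = list(NULL, c("x", "y"))),
                 scale = numeric(0), orientation = numeric(0),
                 response = numeric(0),
                 descriptors = matrix(numeric(0), 0L, 128L)),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("feature_set: %d keypoints\n", nrow(x$keypoints)))
  invisible(x)
}

# Orientation assignment + descriptor computation for keypoints of one
# Gaussian level (all coordinates in octave pixels).
describe_keypoints <- function(kp, g) {
  h <- nrow(g); w <- ncol(g)
  gx <- (shift_mat(g, 0L, 1L) - shift_mat(g, 0L, -1L)) / 2
  gy <- (shift_mat(g, 1L, 0L) - shift_mat(g, -1L, 0L)) / 2
  mag <- sqrt(gx^2 + gy^2); ang <- atan2(gy, gx)
  n <- nrow(kp)
  ori <- numeric(n); keepmask <- logical(n)
  desc <- matrix(0, n, 128L)
  for (i in seq_len(n)) {
    sig <- kp$sigma_oct[i]
    cx <- kp$x[i]; cy <- kp$y[i]
    # -- orientation: 36-bin weighted histogram
    r <- max(3L, round(4.5 * sig))
    x0 <- max(0L, round(cx) - r); x1 <- min(w - 1L, round(cx) + r)
    y0 <- max(0L, round(cy) - r); y1 <- min(h - 1L, round(cy) + r)
    if (x1 - x0 < 2L || y1 - y0 < 2L) next
    xs <- x0:x1; ys <- y0:y1
    M <- mag[ys + 1L, xs + 1L, drop = FALSE]
    A <- ang[ys + 1L, xs + 1L, drop = FALSE]
    DX <- matrix(xs - cx, nrow = length(ys), ncol = length(xs), byrow = TRUE)
    DY <- matrix(ys - cy, nrow = length(ys), ncol = length(xs))
    Wg <- exp(-(DX^2 + DY^2) / (2 * (1.5 * sig)^2))
    bins <- (floor((A + pi) / (2 * pi) * 36) %% 36) + 1L
    hist <- wt_bincount(as.vector(bins), as.vector(M * Wg), 36L)
    hist <- (hist + hist[c(36, 1:35)] + hist[c(2:36, 1)]) / 3   # smooth
    pk <- which.max(hist)
    l <- hist[ifelse(pk == 1L, 36L, pk - 1L)]
    rgt <- hist[ifelse(pk == 36L, 1L, pk + 1L)]
    denom <- l - 2 * hist[pk] + rgt
    off <- if (abs(denom) > 1e-12) 0.5 * (l - rgt) / denom else 0
    theta <- ((pk - 1 + off) / 36) * 2 * pi - pi
    ori[i] <- theta
    # -- descriptor: 4x4 spatial x 8 orientation bins, rotation normalized
    hw <- 3 * sig                       # histogram cell width
    rad <- min(max(4L, round(hw * 2.5 * sqrt(2))), 40L)
    x0 <- max(0L, round(cx) - rad); x1 <- min(w - 1L, round(cx) + rad)
    y0 <- max(0L, round(cy) - rad); y1 <- min(h - 1L, round(cy) + rad)
    xs <- x0:x1; ys <- y0:y1
    M <- mag[ys + 1L, xs + 1L, drop = FALSE]
    A <- ang[ys + 1L, xs + 1L, drop = FALSE]
    DX <- matrix(xs - cx, nrow = length(ys), ncol = length(xs), byrow = TRUE)
    DY <- matrix(ys - cy, nrow = length(ys), ncol = length(xs))
    ct <- cos(theta); st <- sin(theta)
    U <- ( ct * DX + st * DY) / hw      # rotated coords in bin units
    V <- (-st * DX + ct * DY) / hw
    inwin <- abs(U) < 2.5 & abs(V) < 2.5
    if (!any(inwin)) next
    u <- U[inwin] + 1.5; v <- V[inwin] + 1.5   # bin coords 0..3 at centers
    wgt <- (M * exp(-(U^2 + V^2) / 8))[inwin]
    rel <- (A[inwin] - theta) %% (2 * pi)
    ob <- rel / (2 * pi) * 8                   # orientation bin coord
    d <- accumulate_descriptor(u, v, ob, wgt)
    d <- d / max(sqrt(sum(d^2)), 1e-12)
    d <- pmin(d, 0.2)
    desc[i, ] <- d / max(sqrt(sum(d^2)), 1e-12)
    keepmask[i] <- TRUE
  }
  kp$orientation <- ori
  list(kp = kp[keepmask, , drop = FALSE], desc = desc[keepmask, , drop = FALSE])
}

# Trilinear accumulation into the 4x4x8 histogram (vectorized over samples).
accumulate_descriptor <- function(u, v, ob, wgt) {
  d <- numeric(128L)
  u0 <- floor(u); v0 <- floor(v); o0 <- floor(ob)
  fu <- u - u0; fv <- v - v0; fo <- ob - o0
  for (du in 0:1) for (dv in 0:1) for (do in 0:1) {
    uu <- u0 + du; vv <- v0 + dv; oo <- (o0 + do) %% 8
    ok <- uu >= 0 & uu <= 3 & vv >= 0 & vv <= 3
    if (!any(ok)) next
    wts <- wgt * ifelse(du == 1, fu, 1 - fu) *
                 ifelse(dv == 1, fv, 1 - fv) *
                 ifelse(do == 1, fo, 1 - fo)
    idx <- (vv * 4 + uu) * 8 + oo + 1
    d <- d + wt_bincount(idx[ok], wts[ok], 128L)
  }
  d
}

# ---- matching ---------------------------------------------------------------

# Minimal-model fits used inside RANSAC and for the final refit.
fit_model_pts <- function(pa, pb, model) {
  n <- nrow(pa)
  if (model == "translation") {
    affine_translation(mean(pb[, 1] - pa[, 1]), mean(pb[, 2] - pa[, 2]))
  } else if (model == "rigid") {
    # linear similarity: [a -b; b a] + t, 4 parameters
    X <- rbind(cbind(pa[, 1], -pa[, 2], 1, 0),
               cbind(pa[, 2],  pa[, 1], 0, 1))
    yv <- c(pb[, 1], pb[, 2])
    cf <- qr.coef(qr(X), yv)
    affine2d(cf[1], -cf[2], cf[2], cf[1], cf[3], cf[4])
  } else {
    fit_affine(point_match_set("a", "b", pa, pb))
  }
}

min_model_size <- function(model)
  switch(model, translation = 1L, rigid = 2L, affine = 3L)

#' Match two feature sets
#'
#' Descriptor nearest-neighbor matching under Lowe's ratio test (default
#' 0.8), followed by RANSAC consensus under the requested transform model.
#' Returns the inlier correspondences with weight 1; an empty set (never an
#' error) when no consistent model is found, so the caller decides how to
#' treat unmatched pairs.
#'
#' @param fa,fb \code{feature_set}s of the two tiles.
#' @param model RANSAC transform model: \code{"translation"}, \code{"rigid"}
#'   (similarity) or \code{"affine"}.
#' @param ratio Lowe ratio-test threshold on descriptor distances.
#' @param inlier_radius RANSAC inlier radius in pixels.
#' @param n_iter RANSAC iterations.
#' @param seed RNG seed for RANSAC sampling (restores the caller's RNG
#'   state).
#' @param min_inliers Minimum consensus size; a smaller consensus is
#'   reported as an empty set (guards against spurious agreement between
#'   unrelated or barely overlapping tiles).
#' @param tile_id_a,tile_id_b Ids recorded in the returned match set.
#' @return A \code{point_match_set} of inliers (possibly empty).
#' @export
match_features <- function(fa, fb, model = "affine", ratio = 0.8,
                           inlier_radius = 3, n_iter = 1000L, seed = 1234L,
                           min_inliers = 5L, tile_id_a = "a", tile_id_b = "b") {
  empty <- point_match_set(tile_id_a, tile_id_b,
                           matrix(numeric(0), 0, 2), matrix(numeric(0), 0, 2),
                           numeric(0))
  na <- nrow(fa$keypoints); nb <- nrow(fb$keypoints)
  if (na == 0L || nb < 2L) return(empty)
  D2 <- outer(rowSums(fa$descriptors^2), rowSums(fb$descriptors^2), "+") -
    2 * tcrossprod(fa$descriptors, fb$descriptors)
  D2 <- pmax(D2, 0)
  nn1 <- max.col(-D2, ties.method = "first")
  d1 <- D2[cbind(seq_len(na), nn1)]
  D2[cbind(seq_len(na), nn1)] <- Inf
  d2 <- D2[cbind(seq_len(na), max.col(-D2, ties.method = "first"))]
  pass <- sqrt(d1) < ratio * sqrt(d2)
  if (!any(pass)) return(empty)
  pa <- fa$keypoints[pass, , drop = FALSE]
  pb <- fb$keypoints[nn1[pass], , drop = FALSE]
  dup <- duplicated(cbind(pa, pb))
  pa <- pa[!dup, , drop = FALSE]; pb <- pb[!dup, , drop = FALSE]
  m <- min_model_size(model)
  n <- nrow(pa)
  if (n < m) return(empty)
  inl <- with_seed(seed, ransac_inliers(pa, pb, model, inlier_radius, n_iter))
  if (length(inl) < max(m, min_inliers)) return(empty)
  point_match_set(tile_id_a, tile_id_b,
                  pa[inl, , drop = FALSE], pb[inl, , drop = FALSE])
}

ransac_inliers <- function(pa, pb, model, radius, n_iter) {
  n <- nrow(pa); m <- min_model_size(model)
  best <- integer(0)
  r2 <- radius^2
  for (it in seq_len(n_iter)) {
    s <- sample.int(n, m)
    T <- tryCatch(fit_model_pts(pa[s, , drop = FALSE], pb[s, , drop = FALSE],
                                model),
                  error = function(e) NULL)
    if (is.null(T)) next
    d <- affine_apply(T, pa) - pb
    inl <- which(d[, 1]^2 + d[, 2]^2 < r2)
    if (length(inl) > length(best)) best <- inl
  }
  if (length(inl <- best) >= m) {
    # one refit-and-reselect pass on the consensus set
    T <- tryCatch(fit_model_pts(pa[inl, , drop = FALSE],
                                pb[inl, , drop = FALSE], model),
                  error = function(e) NULL)
    if (!is.null(T)) {
      d <- affine_apply(T, pa) - pb
      best <- which(d[, 1]^2 + d[, 2]^2 < r2)
    }
  }
  best
}
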