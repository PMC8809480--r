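# Weighted point correspondences between two tiles (or two sections) and the
# weighted least-squares affine fit on them. Point matches are the solver's
# only input: every registration in the pipeline reduces to minimizing the
# squared distance between corresponding points.

#' Construct a point match set
#'
#' @param tile_id_a,tile_id_b Ids of the two tiles the points live in.
#' @param pa,pb n-by-2 matrices of corresponding points, each in its tile's
#'   local pixel frame (row i of \code{pa} corresponds to row i of \code{pb}).
#' @param weights Per-pair weights in \code{[0, 1]}; default 1.
#' @return An object of class \code{point_match_set}.
#' @export
point_match_set <- function(tile_id_a, tile_id_b, pa, pb,
                            weights = rep(1, nrow(pa))) {
  if (is.null(dim(pa))) pa <- matrix(pa, ncol = 2L)
  if (is.null(dim(pb))) pb <- matrix(pb, ncol = 2L)
  pa <- as.matrix(pa); pb <- as.matrix(pb)
  stopifnot(ncol(pa) == 2L, ncol(pb) == 2L, nrow(pa) == nrow(pb),
            length(weights) == nrow(pa),
            all(weights >= 0), all(weights <= 1))
  if (nrow(pa) > 0L && anyDuplicated(cbind(pa, pb)))
    stop("duplicate point pairs in match set ", tile_id_a, " ~ ", tile_id_b)
  structure(list(tile_id_a = tile_id_a, tile_id_b = tile_id_b,
                 pa = pa, pb = pb, weights = as.numeric(weights)),
            class = "point_match_set")
}

#' @export
print.point_match_set <- function(x, ...) {
  cat(sprintf("point_match_set %s ~ %s: %d pairs\n",
              x$tile_id_a, x$tile_id_b, nrow(x$pa)))
  invisible(x)
}

#' Weighted least-squares affine fit on point correspondences
#'
#' Finds the \code{affine2d} minimizing
#' \eqn{\sum_i w_i \lVert A p_i + t - q_i \rVert^2} over matched pairs
#' \eqn{(p_i, q_i)}. The x and y rows decouple into two 3-parameter linear
#' least-squares problems solved by QR.
#'
#' @param matches A \code{point_match_set} with at least 3 non-collinear
#'   pairs.
#' @return The fitted \code{affine2d} mapping frame a points onto frame b.
#' @export
fit_affine <- function(matches) {
  pa <- matches$pa; pb <- matches$pb; w <- matches$weights
  keep <- w > 0
  pa <- pa[keep, , drop = FALSE]; pb <- pb[keep, , drop = FALSE]; w <- w[keep]
  if (nrow(pa) < 3L)
    stop("rank-deficient fit: need >= 3 weighted pairs, have ", nrow(pa))
  sw <- sqrt(w)
  X <- cbind(pa, 1) * sw
  qrX <- qr(X)
  if (qrX$rank < 3L)
    stop("rank-deficient fit: support points are collinear")
  cx <- qr.coef(qrX, pb[, 1L] * sw)
  cy <- qr.coef(qrX, pb[, 2L] * sw)
  affine2d(cx[1L], cx[2L], cy[1L], cy[2L], cx[3L], cy[3L])
}

#' Root-mean-square residual of a transform against a match set
#' @param T An \code{affine2d} candidate mapping frame a to frame b.
#' @param matches A \code{point_match_set}.
#' @return RMS of the weighted residual norms (pixels).
#' @export
match_rms <- function(T, matches) {
  if (nrow(matches$pa) == 0L) return(NA_real_)
  d <- affine_apply(T, matches$pa) - matches$pb
  sqrt(sum(matches$weights * rowSums(d^2)) / sum(matches$weights))
}
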