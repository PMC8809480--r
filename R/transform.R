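# 2D affine transforms: the universal currency of the pipeline.
# Convention: column points, p' = A %*% p + t, coordinates 0-based,
# x to the right, y down. Serialized row-major as [a11, a12, tx, a21, a22, ty].

#' Construct a 2D affine transform
#'
#' A planar affine map \code{p' = A p + t} with linear part
#' \code{A = [a11 a12; a21 a22]} and translation \code{t = (tx, ty)} in world
#' pixels. Every tile in a store carries one of these into its section's world
#' frame (the high-magnification EM pixel grid, 5 nm per pixel by default).
#'
#' @param a11,a12,a21,a22 Linear part (dimensionless).
#' @param tx,ty Translation (world pixels).
#' @return An object of class \code{affine2d}.
#' @examples
#' T <- affine2d(1, 0, 0, 1, 5, -3)
#' affine_apply(T, cbind(0, 0))
#' @export
affine2d <- function(a11 = 1, a12 = 0, a21 = 0, a22 = 1, tx = 0, ty = 0) {
  v <- c(a11, a12, a21, a22, tx, ty)
  stopifnot(length(v) == 6L, all(is.finite(v)))
  structure(list(a11 = a11, a12 = a12, a21 = a21, a22 = a22, tx = tx, ty = ty),
            class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat(sprintf("affine2d: [%.6g %.6g | %.6g]\n          [%.6g %.6g | %.6g]\n",
              x$a11, x$a12, x$tx, x$a21, x$a22, x$ty))
  invisible(x)
}

#' Identity transform
#' @return \code{affine2d} identity.
#' @export
affine_identity <- function() affine2d()

#' Pure translation
#' @param tx,ty Offsets in world pixels.
#' @return \code{affine2d}.
#' @export
affine_translation <- function(tx, ty) affine2d(1, 0, 0, 1, tx, ty)

#' Similarity transform (isotropic scale + rotation + translation)
#' @param scale Isotropic scale factor.
#' @param angle Rotation angle in radians (counter-clockwise in the
#'   x-right/y-down frame appears clockwise on screen; the algebra is
#'   the usual rotation matrix).
#' @param tx,ty Translation.
#' @return \code{affine2d}.
#' @export
affine_similarity <- function(scale = 1, angle = 0, tx = 0, ty = 0) {
  affine2d(scale * cos(angle), -scale * sin(angle),
           scale * sin(angle),  scale * cos(angle), tx, ty)
}

#' Determinant of the linear part
#' @param T An \code{affine2d}.
#' @return Numeric determinant.
#' @export
affine_det <- function(T) T$a11 * T$a22 - T$a12 * T$a21

#' Compose two affine transforms
#'
#' \code{affine_apply(affine_compose(outer, inner), p)} equals
#' \code{affine_apply(outer, affine_apply(inner, p))}: \code{inner} is applied
#' first. Used to chain the cross-modal (FM to EM-low) and cross-spatial
#' (EM-low to world) registrations into a single FM-to-world overlay map.
#'
#' @param outer,inner \code{affine2d} transforms.
#' @return The composite \code{affine2d}.
#' @export
affine_compose <- function(outer, inner) {
  affine2d(outer$a11 * inner$a11 + outer$a12 * inner$a21,
           outer$a11 * inner$a12 + outer$a12 * inner$a22,
           outer$a21 * inner$a11 + outer$a22 * inner$a21,
           outer$a21 * inner$a12 + outer$a22 * inner$a22,
           outer$a11 * inner$tx + outer$a12 * inner$ty + outer$tx,
           outer$a21 * inner$tx + outer$a22 * inner$ty + outer$ty)
}

#' Invert an affine transform
#' @param T An invertible \code{affine2d}.
#' @return The inverse \code{affine2d}.
#' @export
affine_invert <- function(T) {
  d <- affine_det(T)
  if (!is.finite(d) || abs(d) < 1e-14)
    stop("singular transform: determinant ", d, " is not invertible")
  i11 <-  T$a22 / d; i12 <- -T$a12 / d
  i21 <- -T$a21 / d; i22 <-  T$a11 / d
  affine2d(i11, i12, i21, i22,
           -(i11 * T$tx + i12 * T$ty),
           -(i21 * T$tx + i22 * T$ty))
}

#' Apply an affine transform to points
#'
#' @param T An \code{affine2d}.
#' @param points Numeric n-by-2 matrix of (x, y) rows (a length-2 vector is
#'   accepted as a single point).
#' @return n-by-2 matrix of transformed points.
#' @export
affine_apply <- function(T, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L)
  cbind(T$a11 * points[, 1L] + T$a12 * points[, 2L] + T$tx,
        T$a21 * points[, 1L] + T$a22 * points[, 2L] + T$ty)
}

#' Serialize to row-major coefficient vector
#' @param T An \code{affine2d}.
#' @return Numeric vector \code{c(a11, a12, tx, a21, a22, ty)}.
#' @export
affine_coefs <- function(T) c(T$a11, T$a12, T$tx, T$a21, T$a22, T$ty)

#' Build a transform from a row-major coefficient vector
#' @param v Numeric vector \code{c(a11, a12, tx, a21, a22, ty)}.
#' @return \code{affine2d}.
#' @export
affine_from_coefs <- function(v) {
  if (length(v) != 6L)
    stop("malformed transform: expected 6 coefficients, got ", length(v))
  affine2d(v[1L], v[2L], v[4L], v[5L], v[3L], v[6L])
}

#' @rdname affine_coefs
#' @param x An \code{affine2d}.
#' @param ... Unused.
#' @return \code{as.matrix}: the 3x3 homogeneous matrix.
#' @export
as.matrix.affine2d <- function(x, ...) {
  matrix(c(x$a11, x$a12, x$tx,
           x$a21, x$a22, x$ty,
           0,     0,     1), nrow = 3L, byrow = TRUE)
}
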