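# Fiducial-free FM-to-EM registration from cathodoluminescent spot grids.
#
# While the electron beam dwells on a known grid of positions in the
# low-magnification EM frame, the substrate cathodoluminesces; the FM camera
# records the emitted spots with the excitation light off. Localizing each
# spot on the camera and matching it to the known beam position gives point
# correspondences across modalities without any added fiducials, from which
# the FM-pixel to EM-low-pixel affine transform is fitted.

#' Detect cathodoluminescent spots in an FM frame
#'
#' Local maxima exceeding the background mean + 5 sigma (both estimated
#' robustly) are refined to sub-pixel precision by a 2D Gaussian fit; where
#' the fit fails to converge the intensity-weighted centroid of a 7x7
#' background-subtracted window is used instead.
#'
#' @param fm_image FM camera frame, matrix in [0,1].
#' @param n_expected Maximum number of spots to return (strongest first).
#' @return Object of class \code{spot_detections}: \code{centroids}
#'   (n-by-2 sub-pixel x/y), \code{intensities}, \code{residuals} (RMS of
#'   the Gaussian fit, NA where the centroid fallback was used).
#' @export
detect_spots <- function(fm_image, n_expected) {
  stopifnot(n_expected >= 1L)
  h <- nrow(fm_image); w <- ncol(fm_image)
  bg <- stats::median(fm_image)
  sigma <- stats::mad(fm_image)
  thr <- bg + 5 * max(sigma, 1e-4)
  mx <- neigh_extreme(fm_image, pmax)
  idx <- which(fm_image >= mx & fm_image > thr)
  if (!length(idx)) stop("no CL spots found")
  iy <- (idx - 1L) %% h; ix <- (idx - 1L) %/% h
  ord <- order(-fm_image[idx])
  # suppress secondary maxima within 5 px of a stronger one
  keep <- integer(0)
  for (i in ord) {
    if (!length(keep) ||
        all((ix[keep] - ix[i])^2 + (iy[keep] - iy[i])^2 > 25)) keep <- c(keep, i)
    if (length(keep) == n_expected) break
  }
  cen <- matrix(NA_real_, length(keep), 2,
                dimnames = list(NULL, c("x", "y")))
  ints <- numeric(length(keep)); res <- rep(NA_real_, length(keep))
  for (k in seq_along(keep)) {
    cx <- ix[keep[k]]; cy <- iy[keep[k]]
    r <- 4L
    xs <- max(0L, cx - r):min(w - 1L, cx + r)
    ys <- max(0L, cy - r):min(h - 1L, cy + r)
    win <- fm_image[ys + 1L, xs + 1L, drop = FALSE]
    df <- data.frame(x = rep(xs, each = length(ys)),
                     y = rep(ys, times = length(xs)),
                     v = as.vector(win))
    # warnOnly: nls declares failure on zero-residual (noise-free) data even
    # though the parameter estimates are exact; validate the fit explicitly
    fit <- tryCatch(suppressWarnings(
      stats::nls(v ~ b + A * exp(-((x - x0)^2 + (y - y0)^2) / (2 * s2)),
                 data = df,
                 start = list(b = bg, A = max(win) - bg, x0 = cx, y0 = cy,
                              s2 = 4),
                 control = stats::nls.control(maxiter = 100, warnOnly = TRUE))),
      error = function(e) NULL)
    fit_ok <- !is.null(fit) &&
      stats::coef(fit)[["s2"]] > 0 && stats::coef(fit)[["A"]] > 0 &&
      abs(stats::coef(fit)[["x0"]] - cx) <= r &&
      abs(stats::coef(fit)[["y0"]] - cy) <= r &&
      sqrt(mean(stats::residuals(fit)^2)) < 0.1 * max(win - bg)
    if (fit_ok) {
      cf <- stats::coef(fit)
      cen[k, ] <- c(cf[["x0"]], cf[["y0"]])
      ints[k] <- cf[["A"]]
      res[k] <- sqrt(mean(stats::residuals(fit)^2))
    } else {
      # intensity-weighted centroid in a 7x7 window
      xs7 <- max(0L, cx - 3L):min(w - 1L, cx + 3L)
      ys7 <- max(0L, cy - 3L):min(h - 1L, cy + 3L)
      win7 <- pmax(fm_image[ys7 + 1L, xs7 + 1L, drop = FALSE] - bg, 0)
      s <- sum(win7)
      cen[k, ] <- c(sum(outer(rep(1, length(ys7)), xs7) * win7),
                    sum(outer(ys7, rep(1, length(xs7))) * win7)) / s
      ints[k] <- max(win7)
    }
  }
  inb <- cen[, 1] >= 0 & cen[, 1] <= w - 1 & cen[, 2] >= 0 & cen[, 2] <= h - 1
  if (!any(inb)) stop("no CL spots found")
  structure(list(centroids = cen[inb, , drop = FALSE],
                 intensities = ints[inb], residuals = res[inb]),
            class = "spot_detections")
}

#' @export
print.spot_detections <- function(x, ...) {
  cat(sprintf("spot_detections: %d spots\n", nrow(x$centroids)))
  invisible(x)
}

#' Match detected CL spots to known beam positions
#'
#' One-to-one assignment of camera-frame centroids to beam dwell positions:
#' (a) both point sets are normalized (centroid-centered, RMS-radius scaled,
#' principal-axis rotated where the set is anisotropic), (b) mutual nearest
#' neighbors are paired, rejecting pairs farther apart than 0.25 x grid
#' pitch in the normalized frame, (c) one similarity refit-and-rematch pass
#' tightens the pairing under rotation. All accepted pairs get weight 1.
#'
#' @param spots A \code{spot_detections} (>= 3 centroids).
#' @param grid A \code{beam_spot_grid}.
#' @return A \code{point_match_set} with \code{pa} = FM centroids and
#'   \code{pb} = beam positions (EM-low pixels).
#' @export
match_grid <- function(spots, grid) {
  A <- spots$centroids; B <- grid$positions
  if (nrow(A) < 3L) stop("degenerate CL correspondence: fewer than 3 spots")
  pitch <- grid$pitch %||% stats::median(apply(as.matrix(stats::dist(B)), 1,
                                               function(r) min(r[r > 0])))
  norm_set <- function(P, rotate) {
    mu <- colMeans(P); Q <- sweep(P, 2, mu)
    s <- sqrt(mean(rowSums(Q^2)))
    Q <- Q / s
    R <- diag(2)
    if (rotate) {
      v <- eigen(stats::cov(Q), symmetric = TRUE)$vectors[, 1]
      if (v[1] < 0) v <- -v
      R <- rbind(c(v[1], v[2]), c(-v[2], v[1]))
    }
    list(P = Q %*% t(R), mu = mu, s = s)
  }
  aniso <- function(P) {
    ev <- eigen(stats::cov(P), symmetric = TRUE)$values
    ev[1] / max(ev[2], 1e-12) > 1.5
  }
  # align principal axes only when BOTH sets are anisotropic; rotating one
  # set against an isotropic partner injects an arbitrary rotation
  rot <- aniso(A) && aniso(B)
  na <- norm_set(A, rot); nb <- norm_set(B, rot)
  tol <- 0.25 * pitch / nb$s
  pair_mnn <- function(Pa, Pb, tol) {
    D <- outer(rowSums(Pa^2), rowSums(Pb^2), "+") - 2 * tcrossprod(Pa, Pb)
    ia <- max.col(-D, ties.method = "first")
    ib <- max.col(-t(D), ties.method = "first")
    mutual <- which(ib[ia] == seq_len(nrow(Pa)))
    d <- sqrt(pmax(D[cbind(mutual, ia[mutual])], 0))
    mutual <- mutual[d <= tol]
    cbind(mutual, ia[mutual])
  }
  pr <- pair_mnn(na$P, nb$P, tol)
  if (nrow(pr) >= 2L) {
    # refine by exhaustive mini-RANSAC over the initial pairs: every
    # 2-subset proposes a similarity; the hypothesis that re-pairs the most
    # spots (ties: lowest residual) wins. This tolerates spurious
    # detections and missing spots that contaminate the initial pairing.
    best <- pr; best_n <- -1L; best_rms <- Inf
    subsets <- utils::combn(nrow(pr), 2L)
    for (k in seq_len(ncol(subsets))) {
      s <- subsets[, k]
      Tsim <- tryCatch(fit_model_pts(A[pr[s, 1], , drop = FALSE],
                                     B[pr[s, 2], , drop = FALSE], "rigid"),
                       error = function(e) NULL)
      if (is.null(Tsim)) next
      Am <- affine_apply(Tsim, A)
      cand <- pair_mnn(Am, B, 0.25 * pitch)
      if (nrow(cand) < 2L) next
      rms <- sqrt(mean(rowSums((Am[cand[, 1], , drop = FALSE] -
                                  B[cand[, 2], , drop = FALSE])^2)))
      if (nrow(cand) > best_n || (nrow(cand) == best_n && rms < best_rms)) {
        best <- cand; best_n <- nrow(cand); best_rms <- rms
      }
    }
    pr <- best
  }
  if (nrow(pr) < 3L)
    stop("degenerate CL correspondence: only ", nrow(pr), " accepted pairs")
  point_match_set("fm", "em_low",
                  A[pr[, 1], , drop = FALSE], B[pr[, 2], , drop = FALSE])
}

#' Cross-modal FM-to-EM registration via CL spots
#'
#' Runs \code{\link{detect_spots}}, \code{\link{match_grid}} and
#' \code{\link{fit_affine}} in sequence, returning the FM-pixel to
#' EM-low-pixel affine transform.
#'
#' @param fm_image FM camera frame recorded during the CL scan.
#' @param grid The \code{beam_spot_grid} of beam dwell positions.
#' @return An \code{affine2d} mapping FM pixels to EM-low pixels.
#' @export
register_cross_modal <- function(fm_image, grid) {
  spots <- detect_spots(fm_image, nrow(grid$positions))
  fit_affine(match_grid(spots, grid))
}
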