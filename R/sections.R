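# Serial-section detection on the slide-overview image.
#
# The overview (reflected-light, ~7 um/px) shows every section on the
# ITO-coated slide. The fixed processing order is: (i) input, (ii) contrast
# stretch + grayscale conversion, (iii) intensity threshold -> binary mask,
# (iv) gradient magnitude of the masked grayscale, (v) one marker per
# section at the strongest gradient minima (plus one background marker),
# (vi) marker-controlled watershed flood of the gradient landscape. The
# resulting label map and its stage-coordinate bounding boxes drive
# navigation in the integrated microscope.

rgb_to_gray <- function(img) {
  if (length(dim(img)) == 3L)
    0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
  else img
}

# Linear percentile contrast stretch (1st-99th).
contrast_stretch <- function(g, lo = 0.01, hi = 0.99) {
  q <- stats::quantile(g, c(lo, hi), names = FALSE)
  if (q[2] - q[1] < 1e-9) return(g * 0)
  pmin(pmax((g - q[1]) / (q[2] - q[1]), 0), 1)
}

sobel_magnitude <- function(g) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, byrow = TRUE)
  gx <- EBImage::filter2(g, kx, boundary = "replicate")
  gy <- EBImage::filter2(g, t(kx), boundary = "replicate")
  sqrt(gx^2 + gy^2)
}

#' Segment serial sections on a slide-overview image
#'
#' Marker-controlled watershed instance segmentation: exactly one marker per
#' expected section is seeded at the \code{n_sections} strongest local minima
#' of the masked gradient magnitude (ties broken toward the most interior
#' pixel), separated by a minimum distance, plus one background marker at the
#' point farthest from the foreground mask; the gradient landscape is then
#' flooded from the markers.
#'
#' @param overview RGB array (h-by-w-by-3) or grayscale matrix in [0,1].
#' @param n_sections Expected number of sections (= number of markers).
#' @param overview_pixel_size_um Overview pixel size in micrometers (~7 for
#'   a 30X reflected-light overview).
#' @param markers Optional n-by-2 matrix of user-supplied marker positions
#'   (x, y in 0-based overview pixels), overriding automatic seeding.
#' @param min_marker_dist Minimum distance between automatic markers in
#'   pixels; default scales with the expected per-section mask area.
#' @return An object of class \code{section_label_map}: \code{labels}
#'   (integer matrix, 0 = background, 1..n), \code{n_sections}, \code{boxes}
#'   (n-by-4, 0-based overview pixels, tight), \code{boxes_um} (same in
#'   micrometers relative to the overview origin), \code{pixel_size_um},
#'   \code{markers}.
#' @export
segment_sections <- function(overview, n_sections, overview_pixel_size_um = 7,
                             markers = NULL, min_marker_dist = NULL) {
  if (n_sections < 1L) stop("n_sections must be >= 1")
  n_sections <- as.integer(n_sections)
  g0 <- rgb_to_gray(overview)
  if (min(dim(g0)) < 64L) stop("overview must be larger than 64x64")
  g <- contrast_stretch(g0)                                  # (ii)
  if (stats::sd(g) < 1e-6) stop("insufficient distinct sections: blank overview")
  thr <- EBImage::otsu(EBImage::Image(g))                    # (iii)
  mask <- g > thr
  # small opening removes isolated above-threshold noise pixels
  mask <- matrix(as.logical(EBImage::opening(EBImage::Image(mask * 1),
                                             EBImage::makeBrush(3, "box"))),
                 nrow(mask))
  if (sum(mask) < 16 * n_sections)
    stop("insufficient distinct sections: foreground mask too small")
  grad <- sobel_magnitude(g * mask)                          # (iv)
  grad_s <- gauss_blur(grad, 1)   # watershed landscape

  # (v) marker seeding
  dt <- EBImage::distmap(EBImage::Image(mask * 1))
  dt <- matrix(as.numeric(dt), nrow(mask))
  if (is.null(markers)) {
    if (is.null(min_marker_dist))
      min_marker_dist <- max(6, 0.5 * sqrt(sum(mask) / n_sections))
    interior <- mask & dt > 2
    cand <- which(interior)
    if (length(cand) < n_sections)
      stop("insufficient distinct sections: fewer candidate markers than sections")
    # strongest minima of the seeding gradient first. The seeding gradient is
    # smoothed at the marker-separation scale so texture noise inside a
    # section averages out and each section contributes one broad basin;
    # the quantized-gradient sort then ties across section interiors and the
    # interior-depth tie-break prefers each section's most central point.
    grad_seed <- gauss_blur(grad, max(3, min_marker_dist / 4))
    ord <- cand[order(round(grad_seed[cand] / 0.05), -dt[cand])]
    cy <- ((ord - 1L) %% nrow(mask))
    cx <- ((ord - 1L) %/% nrow(mask))
    sel_x <- numeric(0); sel_y <- numeric(0)
    for (i in seq_along(ord)) {
      if (length(sel_x) == n_sections) break
      if (length(sel_x) == 0L ||
          all((sel_x - cx[i])^2 + (sel_y - cy[i])^2 >= min_marker_dist^2)) {
        sel_x <- c(sel_x, cx[i]); sel_y <- c(sel_y, cy[i])
      }
    }
    if (length(sel_x) < n_sections)
      stop("insufficient distinct sections: only ", length(sel_x),
           " separated markers found for ", n_sections, " sections")
    markers <- cbind(x = sel_x, y = sel_y)
  } else {
    markers <- as.matrix(markers)
    if (nrow(markers) != n_sections)
      stop("need exactly n_sections user-supplied markers")
  }
  # order markers row-major (top-to-bottom, left-to-right) for stable labels;
  # rows are groups separated by y gaps larger than half the marker distance
  oy <- order(markers[, 2])
  ys <- markers[oy, 2]
  row_gap <- 0.5 * sqrt(length(g) / n_sections)
  rowid <- cumsum(c(1, diff(ys) > row_gap))
  ord <- oy[order(rowid, markers[oy, 1])]
  markers <- markers[ord, , drop = FALSE]
  seeds <- matrix(0L, nrow(mask), ncol(mask))
  seeds[cbind(round(markers[, 2]) + 1L, round(markers[, 1]) + 1L)] <-
    seq_len(n_sections)
  bg_dt <- matrix(as.numeric(EBImage::distmap(EBImage::Image((!mask) * 1))),
                  nrow(mask))
  bg_dt[mask] <- -Inf
  bgpos <- which.max(bg_dt)
  seeds[bgpos] <- n_sections + 1L
  # (vi) watershed flood of the gradient landscape from the markers
  lab <- EBImage::propagate(EBImage::Image(grad_s), EBImage::Image(seeds),
                            lambda = 1e-4)
  lab <- matrix(as.integer(lab), nrow(mask))
  lab[lab == n_sections + 1L | !mask] <- 0L
  # keep only each label's largest connected component (stray mask islands
  # in the background otherwise inherit the label of the nearest section)
  for (l in seq_len(n_sections)) {
    cc <- EBImage::bwlabel(EBImage::Image((lab == l) * 1))
    cc <- matrix(as.integer(cc), nrow(lab))
    if (max(cc) > 1L) {
      keep <- which.max(tabulate(cc[cc > 0L]))
      lab[lab == l & cc != keep] <- 0L
    }
  }
  found <- sort(setdiff(unique(as.vector(lab)), 0L))
  if (length(found) != n_sections)
    stop("insufficient distinct sections: watershed yielded ",
         length(found), " of ", n_sections, " labels")
  boxes <- t(vapply(seq_len(n_sections), function(l) {
    idx <- which(lab == l)
    ys <- (idx - 1L) %% nrow(lab); xs <- (idx - 1L) %/% nrow(lab)
    c(min(xs), min(ys), max(xs), max(ys))
  }, numeric(4)))
  colnames(boxes) <- c("xmin", "ymin", "xmax", "ymax")
  structure(list(labels = lab, n_sections = n_sections, boxes = boxes,
                 boxes_um = boxes * overview_pixel_size_um,
                 pixel_size_um = overview_pixel_size_um, markers = markers),
            class = "section_label_map")
}

#' @export
print.section_label_map <- function(x, ...) {
  cat(sprintf("section_label_map: %d sections on %dx%d overview (%g um/px)\n",
              x$n_sections, ncol(x$labels), nrow(x$labels), x$pixel_size_um))
  invisible(x)
}

#' Convert label-map bounding boxes to stage coordinates
#'
#' Stage-frame boxes are the pixel boxes scaled by the overview pixel size
#' and shifted by the stage position of the overview origin; these are what
#' gets handed to the microscope for per-section navigation.
#'
#' @param map A \code{section_label_map}.
#' @param overview_origin_um Stage position (x, y in um) of overview pixel
#'   (0, 0).
#' @return n-by-4 matrix of stage-frame boxes in micrometers, label order.
#' @export
boxes_to_stage <- function(map, overview_origin_um = c(0, 0)) {
  b <- map$boxes * map$pixel_size_um
  b[, c(1, 3)] <- b[, c(1, 3)] + overview_origin_um[1]
  b[, c(2, 4)] <- b[, c(2, 4)] + overview_origin_um[2]
  b
}
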