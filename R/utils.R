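# Shared internal helpers: seeded RNG scopes, deterministic seed fan-out,
# and bilinear raster sampling in the package's 0-based pixel convention.

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Stable 31-adic string hash into [0, 2^31 - 2]; used to fan a single global
# seed out into independent per-component seeds so regenerating one fixture
# does not perturb the random stream of another.
stable_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  h
}

#' Derive a component seed from a global seed
#'
#' Deterministic fan-out of one user-facing seed into per-component seeds by
#' stable string hashing, so each synthetic generator draws from its own
#' stream.
#'
#' @param seed Integer global seed.
#' @param component Character tag naming the consumer.
#' @return Integer seed in \code{[0, 2^31 - 2]}.
#' @export
derive_seed <- function(seed, component) {
  (as.numeric(seed) %% 2147483647 * 1000003 + stable_hash(component)) %% 2147483647
}

# Bilinear sample of matrix img (rows = y, cols = x) at 0-based coordinates
# (x, y); pixel centers sit at integer coordinates. Points outside the image
# return `outside` (default 0).
sample_bilinear <- function(img, x, y, outside = 0) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0;   fy <- y - y0
  inside <- x >= 0 & y >= 0 & x <= w - 1 & y <= h - 1
  # clamp the corner indices so arithmetic stays in range; masked afterwards
  x0c <- pmin(pmax(x0, 0), w - 1); x1c <- pmin(x0c + 1, w - 1)
  y0c <- pmin(pmax(y0, 0), h - 1); y1c <- pmin(y0c + 1, h - 1)
  i00 <- y0c + 1 + h * x0c; i10 <- y0c + 1 + h * x1c
  i01 <- y1c + 1 + h * x0c; i11 <- y1c + 1 + h * x1c
  v <- (1 - fx) * (1 - fy) * img[i00] + fx * (1 - fy) * img[i10] +
       (1 - fx) * fy       * img[i01] + fx * fy       * img[i11]
  v[!inside] <- outside
  v
}

# Block-average downsample by an integer factor (trims the remainder).
downsample_mean <- function(img, factor) {
  if (factor == 1) return(img)
  h <- (nrow(img) %/% factor) * factor
  w <- (ncol(img) %/% factor) * factor
  img <- img[seq_len(h), seq_len(w), drop = FALSE]
  a <- array(img, dim = c(factor, h %/% factor, factor, w %/% factor))
  colMeans(aperm(a, c(1, 3, 2, 4)), dims = 2)
}

# Axis-aligned box utilities; boxes are c(xmin, ymin, xmax, ymax).
box_intersects <- function(a, b) {
  a[1] <= b[3] && b[1] <= a[3] && a[2] <= b[4] && b[2] <= a[4]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
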