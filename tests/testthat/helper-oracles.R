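# Independent dense oracles for the package's least-squares machinery.
# These deliberately share no code with the package: fits are computed by
# dense normal equations via qr.solve on explicitly constructed matrices.

# Dense weighted affine fit: minimize sum w_i ||A p_i + t - q_i||^2.
# Returns coefficients c(a11, a12, tx, a21, a22, ty).
oracle_affine_fit <- function(pa, pb, w = rep(1, nrow(pa))) {
  X <- cbind(pa[, 1], pa[, 2], 1)
  W <- diag(w, nrow(pa))
  cx <- qr.solve(t(X) %*% W %*% X, t(X) %*% W %*% pb[, 1])
  cy <- qr.solve(t(X) %*% W %*% X, t(X) %*% W %*% pb[, 2])
  c(cx[1], cx[2], cx[3], cy[1], cy[2], cy[3])
}

# Dense replica of the regularized correspondence solve. Builds the full
# design matrix (data rows T_a(p) - T_b(q) = 0, regularization rows
# sqrt(lambda) (theta - theta_init), anchor parameters substituted as
# constants) and solves the normal equations densely.
oracle_solve <- function(tiles, matches, model, lambda, anchor) {
  ids <- vapply(tiles, function(t) t$tile_id, "")
  init <- lapply(tiles, function(t) t$transform)
  names(init) <- ids
  np <- switch(model, translation = 2L, rigid = 4L, affine = 6L)
  par_of <- function(T) switch(model,
    translation = c(T$tx, T$ty),
    rigid = c(T$a11, T$a21, T$tx, T$ty),
    affine = c(T$a11, T$a12, T$a21, T$a22, T$tx, T$ty))
  rows_of <- function(p, T0) {
    x <- p[, 1]; y <- p[, 2]; n <- length(x); one <- rep(1, n); z <- rep(0, n)
    switch(model,
      translation = list(Ax = cbind(one, z), Ay = cbind(z, one),
                         cx = T0$a11 * x + T0$a12 * y,
                         cy = T0$a21 * x + T0$a22 * y),
      rigid = list(Ax = cbind(x, -y, one, z), Ay = cbind(y, x, z, one),
                   cx = z, cy = z),
      affine = list(Ax = cbind(x, y, z, z, one, z),
                    Ay = cbind(z, z, x, y, z, one), cx = z, cy = z))
  }
  free <- setdiff(ids, anchor)
  col0 <- stats::setNames((seq_along(free) - 1L) * np, free)
  ncols <- length(free) * np
  A <- matrix(0, 0, ncols); b <- numeric(0)
  for (m in matches) {
    n <- nrow(m$pa)
    if (n == 0L) next
    sw <- sqrt(m$weights)
    ra <- rows_of(m$pa, init[[m$tile_id_a]])
    rb <- rows_of(m$pb, init[[m$tile_id_b]])
    for (axis in c("x", "y")) {
      Aa <- if (axis == "x") ra$Ax else ra$Ay
      Ab <- if (axis == "x") rb$Ax else rb$Ay
      bv <- ((if (axis == "x") rb$cx else rb$cy) -
             (if (axis == "x") ra$cx else ra$cy)) * sw
      blk <- matrix(0, n, ncols)
      if (m$tile_id_a %in% free)
        blk[, col0[m$tile_id_a] + seq_len(np)] <- Aa * sw
      else bv <- bv - (Aa %*% par_of(init[[m$tile_id_a]]))[, 1] * sw
      if (m$tile_id_b %in% free)
        blk[, col0[m$tile_id_b] + seq_len(np)] <- -Ab * sw
      else bv <- bv + (Ab %*% par_of(init[[m$tile_id_b]]))[, 1] * sw
      A <- rbind(A, blk); b <- c(b, bv)
    }
  }
  if (lambda > 0) for (id in free) {
    blk <- matrix(0, np, ncols)
    blk[, col0[id] + seq_len(np)] <- diag(sqrt(lambda), np)
    A <- rbind(A, blk); b <- c(b, sqrt(lambda) * par_of(init[[id]]))
  }
  theta <- qr.solve(t(A) %*% A, t(A) %*% b)[, 1]
  out <- list(); out[[anchor]] <- par_of(init[[anchor]])
  for (id in free) out[[id]] <- theta[col0[id] + seq_len(np)]
  out
}

# Random affine close to identity (for property tests).
random_affine <- function(scale_jitter = 0.05, shear = 0.05, t_range = 10) {
  affine2d(1 + runif(1, -scale_jitter, scale_jitter), runif(1, -shear, shear),
           runif(1, -shear, shear), 1 + runif(1, -scale_jitter, scale_jitter),
           runif(1, -t_range, t_range), runif(1, -t_range, t_range))
}

# Synthetic montage scenario as point correspondences only (no images):
# tiles on a rows x cols grid with hidden true offsets; matches between
# grid neighbors are noisy observations of the truth.
synthetic_match_scenario <- function(rows, cols, pitch = 100,
                                     jitter = function(n) runif(n, -20, 20),
                                     noise_sd = 0.3, n_pts = 12,
                                     section_index = 0L) {
  ids <- outer(seq_len(rows) - 1L, seq_len(cols) - 1L,
               function(r, cc) sprintf("g_z%03d_r%d_c%d", section_index, r, cc))
  img <- matrix(0.5, 64, 64)
  tiles <- list(); truth <- list()
  for (r in seq_len(rows) - 1L) for (cc in seq_len(cols) - 1L) {
    id <- sprintf("g_z%03d_r%d_c%d", section_index, r, cc)
    nom <- c(cc, r) * pitch
    tru <- nom + jitter(2)
    tiles[[id]] <- tile(id, "EM_HIGH", img, section_index = section_index,
                        stage_xy = nom * 5 / 1000,
                        transform = affine_translation(nom[1], nom[2]))
    truth[[id]] <- affine_translation(tru[1], tru[2])
  }
  matches <- list()
  add <- function(ida, idb) {
    pa <- cbind(runif(n_pts, 0, 63), runif(n_pts, 0, 63))
    world <- affine_apply(truth[[ida]], pa)
    pb <- affine_apply(affine_invert(truth[[idb]]), world) +
      matrix(rnorm(2 * n_pts, 0, noise_sd), n_pts)
    matches[[length(matches) + 1L]] <<- point_match_set(ida, idb, pa, pb)
  }
  for (r in seq_len(rows) - 1L) for (cc in seq_len(cols) - 1L) {
    if (cc < cols - 1L) add(sprintf("g_z%03d_r%d_c%d", section_index, r, cc),
                            sprintf("g_z%03d_r%d_c%d", section_index, r, cc + 1L))
    if (r < rows - 1L) add(sprintf("g_z%03d_r%d_c%d", section_index, r, cc),
                           sprintf("g_z%03d_r%d_c%d", section_index, r + 1L, cc))
  }
  list(tiles = unname(tiles), truth = truth, matches = matches, ids = sort(ids))
}

# Max absolute coefficient difference between two transforms.
coef_diff <- function(Ta, Tb) max(abs(affine_coefs(Ta) - affine_coefs(Tb)))

# Max translation error of a solved set vs truth, in pixels.
solution_error <- function(sol, truth) {
  max(vapply(names(truth), function(id)
    sqrt(sum((c(sol[[id]]$tx, sol[[id]]$ty) -
              c(truth[[id]]$tx, truth[[id]]$ty))^2)), 0))
}
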