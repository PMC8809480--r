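# 2D affine transform algebra.

test_that("identity maps points to themselves", {
  # [TRIVIAL]
  p <- cbind(c(0, 3.5, -2), c(1, -4, 7))
  expect_equal(affine_apply(affine_identity(), p), p)
})

test_that("affine_apply matches the hand-computed matrix action", {
  # [DERIVED] A p + t computed by hand: (2*1 + 0.5*2 + 3, -1*1 + 1.5*2 - 4)
  T <- affine2d(2, 0.5, -1, 1.5, 3, -4)
  expect_equal(affine_apply(T, cbind(1, 2)), cbind(6, -2))
})

test_that("composition agrees with matrix multiplication and is associative", {
  set.seed(42)
  for (i in 1:10) {
    Ta <- random_affine(); Tb <- random_affine(); Tc <- random_affine()
    p <- matrix(runif(10, -50, 50), 5)
    # [DERIVED] (Ta o Tb)(p) == Ta(Tb(p))
    expect_equal(affine_apply(affine_compose(Ta, Tb), p),
                 affine_apply(Ta, affine_apply(Tb, p)))
    lhs <- affine_compose(affine_compose(Ta, Tb), Tc)
    rhs <- affine_compose(Ta, affine_compose(Tb, Tc))
    expect_lt(coef_diff(lhs, rhs), 1e-10)
  }
})

test_that("inverse composes to the identity on random transforms", {
  set.seed(7)
  for (i in 1:10) {
    T <- random_affine()
    expect_lt(coef_diff(affine_compose(T, affine_invert(T)),
                        affine_identity()), 1e-9)
    expect_lt(coef_diff(affine_compose(affine_invert(T), T),
                        affine_identity()), 1e-9)
  }
})

test_that("similarity transform has the expected determinant and action", {
  # [DERIVED] det of a scale-s rotation is s^2; rotating (1,0) by 90 degrees
  # in a y-down frame gives (0,1)
  T <- affine_similarity(scale = 2, angle = pi / 2)
  expect_equal(affine_det(T), 4)
  expect_equal(affine_apply(T, cbind(1, 0)), cbind(0, 2), tolerance = 1e-12)
})

test_that("coefficient serialization round-trips row-major", {
  T <- affine2d(1.1, 0.2, -0.3, 0.9, 5, -7)
  v <- affine_coefs(T)
  # [TRIVIAL] row-major layout [a11, a12, tx, a21, a22, ty]
  expect_equal(v, c(1.1, 0.2, 5, -0.3, 0.9, -7))
  expect_lt(coef_diff(affine_from_coefs(v), T), 1e-15)
})

test_that("malformed and singular transforms are rejected", {
  expect_error(affine_from_coefs(c(1, 0, 0)), "malformed transform")
  expect_error(affine_invert(affine2d(1, 2, 2, 4, 0, 0)), "singular transform")
})

test_that("translation gauge: conjugating by a scale rescales translations", {
  # [DERIVED] S T S^-1 for S = diag(s) scales tx, ty by s and keeps A
  s <- 4
  S <- affine2d(s, 0, 0, s, 0, 0)
  T <- affine2d(1.02, -0.01, 0.03, 0.98, 2.5, -1.5)
  C <- affine_compose(S, affine_compose(T, affine_invert(S)))
  expect_equal(c(C$a11, C$a12, C$a21, C$a22), c(T$a11, T$a12, T$a21, T$a22))
  expect_equal(c(C$tx, C$ty), s * c(T$tx, T$ty))
})
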