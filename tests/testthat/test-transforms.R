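# Rigid-transform algebra and motion-score metrics. The brute-force oracle
# for the rotation displacement maximises |R p - p| over many sampled points
# of the 64 mm sphere, independently of the closed form 2 r sin(theta / 2).

brute_force_displacement <- function(t, radius = 64, n = 2e5) {
  R <- rotation_matrix_zyx(t$rot_deg)
  withr::with_seed(11, {
    p <- matrix(rnorm(3 * n), nrow = 3)
    p <- radius * sweep(p, 2, sqrt(colSums(p^2)), "/")
  })
  max(sqrt(colSums((R %*% p - p)^2)))
}

test_that("rotation matrices are orthonormal and invert exactly", {
  for (t in random_transform_list(25, range = 60, seed = 2)) {
    R <- rotation_matrix_zyx(t$rot_deg)
    expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
    i <- compose(t, invert(t))
    expect_lt(max(abs(c(i$rot_deg, i$trans_mm))), 1e-9)
    i2 <- compose(invert(t), t)
    expect_lt(max(abs(c(i2$rot_deg, i2$trans_mm))), 1e-9)
    tt <- invert(invert(t))
    expect_equal(tt$rot_deg, t$rot_deg, tolerance = 1e-12)
    expect_equal(tt$trans_mm, t$trans_mm, tolerance = 1e-12)
  }
})

test_that("composition follows apply-b-then-a and is associative", {
  t <- rigid_transform(c(3, -7, 5), c(1, -2, 3))
  id <- rigid_transform()
  ct <- compose(t, id)
  expect_equal(ct$rot_deg, t$rot_deg)
  expect_equal(ct$trans_mm, t$trans_mm)
  # pure translations add
  s <- compose(rigid_transform(trans_mm = c(1, 2, 3)),
               rigid_transform(trans_mm = c(10, -1, 0)))
  expect_equal(s$trans_mm, c(11, 1, 3))
  expect_equal(s$rot_deg, c(0, 0, 0))
  # associativity on rotation matrices
  a <- rigid_transform(c(10, 0, 0), c(1, 0, 0))
  b <- rigid_transform(c(0, -8, 0), c(0, 2, 0))
  c3 <- rigid_transform(c(0, 0, 6), c(0, 0, -3))
  l <- compose(compose(a, b), c3)
  r <- compose(a, compose(b, c3))
  expect_equal(l$rot_deg, r$rot_deg, tolerance = 1e-10)
  expect_equal(l$trans_mm, r$trans_mm, tolerance = 1e-10)
  expect_error(compose(a, rigid_transform(center = "other")), "center")
})

test_that("inversion of pure translations negates them", {
  i <- invert(rigid_transform(trans_mm = c(1, 2, 3)))
  expect_equal(i$trans_mm, c(-1, -2, -3))
  i0 <- invert(rigid_transform())
  expect_equal(c(i0$rot_deg, i0$trans_mm), rep(0, 6))
})

test_that("rotation displacement matches the sphere-sampling oracle", {
  expect_equal(rotation_displacement(rigid_transform()), 0)
  expect_equal(rotation_displacement(rigid_transform(c(180, 0, 0))), 128,
               tolerance = 1e-9)
  expect_equal(rotation_displacement(rigid_transform(c(10, 0, 0))),
               2 * 64 * sin(5 * pi / 180), tolerance = 1e-12)
  for (t in random_transform_list(100, range = 30, seed = 7)) {
    closed <- rotation_displacement(t)
    brute <- brute_force_displacement(t)
    expect_lt(abs(closed - brute), 1e-3)
    expect_gte(closed + 1e-9, brute) # sampled max cannot exceed the true max
  }
})

test_that("motion score sums rotational and translational displacement", {
  expect_equal(motion_score(rigid_transform())$score, 0)
  ms <- motion_score(rigid_transform(trans_mm = c(3, 4, 0)))
  expect_equal(ms$score, 5)
  expect_equal(ms$delta_R, 0)
  ms2 <- motion_score(rigid_transform(c(10, 0, 0), c(3, 4, 0)))
  expect_equal(ms2$score, 2 * 64 * sin(5 * pi / 180) + 5, tolerance = 1e-12)
  expect_equal(ms2$score, ms2$delta_R + ms2$translation_norm)
  # zero iff identity
  for (t in random_transform_list(50, range = 10, seed = 3))
    expect_gt(motion_score(t)$score, 0)
})

test_that("residual motion score is zero iff detected equals ground truth", {
  for (t in random_transform_list(100, range = 15, seed = 5))
    expect_lt(residual_motion_score(t, t), 1e-9)
  expect_equal(residual_motion_score(rigid_transform(),
                                     rigid_transform(trans_mm = c(0, 0, 6))), 6)
  # symmetric for pure translations
  a <- rigid_transform(trans_mm = c(1, -4, 2))
  b <- rigid_transform(trans_mm = c(-3, 0, 5))
  expect_equal(residual_motion_score(a, b), residual_motion_score(b, a))
})

test_that("transform JSON round-trips with its conventions", {
  t <- rigid_transform(c(1.25, -3.5, 0.125), c(4.5, -6, 0.25))
  f <- tempfile(fileext = ".json")
  write_transform(t, f)
  t2 <- read_transform(f)
  expect_equal(t2$rot_deg, t$rot_deg)
  expect_equal(t2$trans_mm, t$trans_mm)
  expect_identical(t2$center, "volume_center")
  unlink(f)
})
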