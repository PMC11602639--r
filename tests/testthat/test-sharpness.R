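# Sharpness metrics: variance of the Laplacian and the 75%-to-25% edge width.

brute_laplacian_variance <- function(img) {
  n <- nrow(img); m <- ncol(img)
  out <- c()
  for (i in 2:(n - 1)) for (j in 2:(m - 1))
    out <- c(out, img[i - 1, j] + img[i + 1, j] + img[i, j - 1] +
               img[i, j + 1] - 4 * img[i, j])
  var(out)
}

test_that("variance of Laplacian vanishes on constant and affine images", {
  expect_equal(variance_of_laplacian(matrix(3.7, 9, 9)), 0)
  ramp <- outer(1:10, 1:10, function(i, j) 2 * i - 3 * j + 1)
  expect_equal(variance_of_laplacian(ramp), 0)
  expect_error(variance_of_laplacian(matrix(0, 2, 5)), "3x3")
})

test_that("variance of Laplacian matches brute-force convolution", {
  chk <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  expect_equal(variance_of_laplacian(chk), brute_laplacian_variance(chk))
  withr::with_seed(3, {
    img <- matrix(rnorm(15 * 12), 15, 12)
    expect_equal(variance_of_laplacian(img), brute_laplacian_variance(img))
  })
})

test_that("variance of Laplacian has the documented equivariances", {
  withr::with_seed(5, img <- matrix(runif(100), 10, 10))
  expect_equal(variance_of_laplacian(img + 17), variance_of_laplacian(img))
  expect_equal(variance_of_laplacian(3 * img), 9 * variance_of_laplacian(img))
})

test_that("blur strictly decreases the variance of the Laplacian", {
  sl <- tiny_phantom(c(32, 32, 32), noise_sd = 3, seed = 2)$data[, , 16]
  vols <- vapply(c(0, 1, 2, 3), function(s) {
    img <- if (s == 0) sl else gaussian_smooth(sl, s)
    variance_of_laplacian(img)
  }, numeric(1))
  expect_true(all(diff(vols) < 0))
})

test_that("sharpness ratio behaves as a relative measure", {
  sl <- tiny_phantom(c(32, 32, 32), noise_sd = 0)$data[, , 16]
  expect_equal(sharpness_ratio(sl, sl), 1)
  blur <- gaussian_smooth(sl, 2)
  expect_gt(sharpness_ratio(sl, blur), 1)
  expect_equal(sharpness_ratio(sl, blur), 1 / sharpness_ratio(blur, sl))
  expect_error(sharpness_ratio(sl, matrix(1, 32, 32)), "degenerate")
})

test_that("3D Laplacian variance is available and vanishes on affine volumes", {
  a <- array(0, c(6, 6, 6))
  for (k in 1:6) a[, , k] <- outer(1:6, 1:6, function(i, j) i + 2 * j) + k
  expect_equal(variance_of_laplacian_3d(a), 0)
})

test_that("edge width matches the sigmoid closed form", {
  s <- 1.5
  x <- seq(-15, 15, by = 0.01)
  prof <- 1 / (1 + exp(-x / s))
  w <- profile_edge_width(prof, spacing_mm = 0.01)
  expect_equal(w$width_mm, 2 * s * log(3), tolerance = 0.01)
  # shallower sigmoid -> strictly larger width
  prof2 <- 1 / (1 + exp(-x / (2 * s)))
  w2 <- profile_edge_width(prof2, spacing_mm = 0.01)
  expect_gt(w2$width_mm, w$width_mm)
  # ideal step edge: crossings land inside one sampling interval
  step <- c(rep(1, 10), rep(0, 10))
  ws <- profile_edge_width(step, spacing_mm = 1)
  expect_lte(ws$width_mm, 1)
})

test_that("dip profiles report per-flank widths and the steeper one", {
  x <- seq(-20, 20, by = 0.05)
  dip <- 1 - 0.8 * exp(-x^2 / (2 * 2^2)) # symmetric dip
  w <- profile_edge_width(dip, spacing_mm = 0.05, both = TRUE)
  expect_equal(w$width_left_mm, w$width_right_mm, tolerance = 0.01)
  expect_equal(w$width_mm, min(w$width_left_mm, w$width_right_mm))
  # asymmetric dip: steeper (narrower) flank is reported
  asym <- ifelse(x < 0, 1 - 0.8 * exp(-x^2 / (2 * 1^2)),
                 1 - 0.8 * exp(-x^2 / (2 * 4^2)))
  wa <- profile_edge_width(asym, spacing_mm = 0.05, both = TRUE)
  expect_lt(wa$width_left_mm, wa$width_right_mm)
  expect_equal(wa$width_mm, wa$width_left_mm)
  # a hump has no dip and is not monotone
  expect_error(profile_edge_width(exp(-x^2), 0.05), "not a monotone")
})

test_that("line profiles sample the image where expected", {
  img <- outer(1:20, 1:20, function(i, j) i)
  prof <- line_profile(img, 1, 10, 20, 10, spacing_mm = 2)
  expect_equal(prof$value, seq(1, 20, length.out = nrow(prof)),
               tolerance = 1e-9)
})
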