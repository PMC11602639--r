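# Image-similarity metrics used to drive and evaluate rigid registration of
# fat-navigator volumes: concordance correlation coefficient (CCC), SSIM and
# RMSE. All three accept volume3d objects or bare numeric arrays of matching
# shape and operate on magnitude intensities as-is (no normalisation).

metric_data <- function(x) {
  if (is_volume3d(x)) x$data else x
}

check_same_shape <- function(x, y) {
  if (!identical(dim(x), dim(y)))
    stop("images must have the same shape: ",
         paste(dim(x), collapse = "x"), " vs ", paste(dim(y), collapse = "x"))
}

#' Concordance correlation coefficient between two images
#'
#' Agreement metric combining correlation with mean and variance concordance:
#' `rho_c = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)`, where variances
#' and covariance use population (1/n) normalisation over the (optionally
#' masked) voxels. `rho_c` lies in \[-1, 1\], equals 1 only for identical
#' images, and reduces to the Pearson correlation when the two images share
#' mean and variance. It is the cost function of the sub-volume registration
#' algorithm.
#'
#' @param x,y images of identical shape ([volume3d()] or arrays).
#' @param mask optional logical array selecting the voxels to use (>= 2).
#' @return scalar in \[-1, 1\].
#' @examples
#' ccc(c(0, 2), c(1, 3)) # 2/3
#' @export
ccc <- function(x, y, mask = NULL) {
  x <- metric_data(x); y <- metric_data(y)
  check_same_shape(x, y)
  if (!is.null(mask)) {
    x <- x[mask]; y <- y[mask]
    if (length(x) < 2L) stop("mask must select at least 2 voxels")
  }
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx2 <- sum((x - mx)^2) / n
  sy2 <- sum((y - my)^2) / n
  sxy <- sum((x - mx) * (y - my)) / n
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom <= 0)
    stop("degenerate input: both images constant with equal means")
  2 * sxy / denom
}

#' Root mean squared error between two images
#'
#' `sqrt(mean((x - y)^2))`; zero iff the images are voxel-wise identical.
#'
#' @inheritParams ccc
#' @return non-negative scalar.
#' @export
rmse <- function(x, y) {
  x <- metric_data(x); y <- metric_data(y)
  check_same_shape(x, y)
  sqrt(mean((x - y)^2))
}

# Gaussian-weighted local mean with border clipping: truncated-kernel
# convolution renormalised by the local kernel mass
local_mean <- function(x, kernel) {
  d <- if (is.null(dim(x))) length(x) else dim(x)
  d3 <- c(d, rep(1L, 3 - length(d)))
  num <- cpp_sep_conv3(as.numeric(x), d3, kernel)
  den <- cpp_sep_conv3(rep(1, prod(d3)), d3, kernel)
  array(num / den, dim = d)
}

gaussian_kernel <- function(sigma, width = 11L) {
  half <- (width - 1L) / 2
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Structural similarity index between two images
#'
#' Mean SSIM in the standard Wang et al. formulation: the product of
#' luminance, contrast and structure comparisons over a sliding Gaussian
#' window (sigma 1.5, 11 samples, clipped and renormalised at borders),
#' averaged over the image. Stabilisation constants are `C1 = (0.01 L)^2`,
#' `C2 = (0.03 L)^2`, `C3 = C2 / 2` with `L` the dynamic range of the *first*
#' (reference) image — the one deliberate asymmetry of the metric.
#'
#' @inheritParams ccc
#' @param sigma Gaussian window SD in voxels.
#' @param window window width in samples (odd).
#' @return scalar in \[-1, 1\].
#' @export
ssim <- function(x, y, sigma = 1.5, window = 11L) {
  x <- metric_data(x); y <- metric_data(y)
  check_same_shape(x, y)
  L <- diff(range(x))
  if (L <= 0) L <- 1 # constant reference: fall back to unit dynamic range
  C1 <- (0.01 * L)^2
  C2 <- (0.03 * L)^2
  k <- gaussian_kernel(sigma, as.integer(window))
  mu_x <- local_mean(x, k); mu_y <- local_mean(y, k)
  sxx <- local_mean(x * x, k) - mu_x^2
  syy <- local_mean(y * y, k) - mu_y^2
  sxy <- local_mean(x * y, k) - mu_x * mu_y
  # with C3 = C2/2 the contrast and structure terms collapse to one factor
  s_map <- ((2 * mu_x * mu_y + C1) * (2 * sxy + C2)) /
           ((mu_x^2 + mu_y^2 + C1) * (sxx + syy + C2))
  mean(s_map)
}

#' Similarity-metric profile under a single-parameter perturbation
#'
#' Sweeps one rigid-motion parameter (a translation in mm or a rotation in
#' degrees) over the given offsets, applying the perturbation to `moving` and
#' evaluating the chosen metric against `fixed` at each offset. The resulting
#' curve characterises the metric's basin of attraction — peak sharpness and
#' the number of local extrema — around a candidate alignment.
#'
#' @param fixed,moving [volume3d()] objects of identical shape.
#' @param metric one of `"CCC"`, `"SSIM"`, `"RMSE"`.
#' @param parameter one of `"tx"`, `"ty"`, `"tz"` (mm), `"rz"`, `"ry"`,
#'   `"rx"` (degrees).
#' @param offsets strictly increasing numeric vector of parameter offsets.
#' @param interp interpolation used for the perturbation.
#' @return A data frame of class `metric_profile` with columns `offset` and
#'   `value`, and attributes `metric` and `parameter`.
#' @export
metric_profile <- function(fixed, moving, metric = "CCC", parameter = "tx",
                           offsets, interp = "trilinear") {
  metric <- match.arg(metric, c("CCC", "SSIM", "RMSE"))
  parameter <- match.arg(parameter, c("tx", "ty", "tz", "rz", "ry", "rx"))
  offsets <- as.numeric(offsets)
  if (length(offsets) == 0L) stop("`offsets` must be non-empty")
  if (any(diff(offsets) <= 0)) stop("`offsets` must be strictly increasing")
  fn <- switch(metric, CCC = ccc, SSIM = ssim, RMSE = rmse)
  vals <- vapply(offsets, function(o) {
    t <- param_transform(parameter, o)
    pert <- apply_rigid_transform(moving, t, interp = interp)
    fn(fixed, pert)
  }, numeric(1))
  structure(data.frame(offset = offsets, value = vals),
            metric = metric, parameter = parameter,
            class = c("metric_profile", "data.frame"))
}

param_transform <- function(parameter, value) {
  rot <- c(0, 0, 0); tr <- c(0, 0, 0)
  i <- match(parameter, c("tx", "ty", "tz", "rz", "ry", "rx"))
  if (i <= 3) tr[i] <- value else rot[i - 3] <- value
  rigid_transform(rot, tr)
}

#' Count strict local maxima of a metric profile
#'
#' @param profile a [metric_profile()] (or any data frame with a `value`
#'   column).
#' @return integer count of interior strict local maxima.
#' @export
count_local_maxima <- function(profile) {
  v <- profile$value
  if (length(v) < 3L) return(0L)
  sum(v[2:(length(v) - 1)] > v[1:(length(v) - 2)] &
      v[2:(length(v) - 1)] > v[3:length(v)])
}

#' Gaussian smoothing of an image or volume
#'
#' Separable Gaussian filter with border clipping (the truncated kernel is
#' renormalised near edges, so constant images stay constant).
#'
#' @param x [volume3d()], matrix or 3D array.
#' @param sigma Gaussian SD in voxels.
#' @param width kernel width in samples (odd; default covers 3 sigma).
#' @return same type as the input.
#' @export
gaussian_smooth <- function(x, sigma, width = 2L * ceiling(3 * sigma) + 1L) {
  k <- gaussian_kernel(sigma, as.integer(width))
  if (is_volume3d(x)) {
    out <- x
    out$data <- local_mean(x$data, k)
    out
  } else {
    local_mean(x, k)
  }
}
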