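#' Specification of a fat-navigator-like head phantom
#'
#' Describes a digital phantom that mimics the defining feature of a fat-only
#' head navigator: a bright ellipsoidal shell of subcutaneous (scalp) fat on a
#' dark interior/background, optionally with bright blobs standing in for
#' facial fat pads, plus additive noise. Defaults follow a 2 mm isotropic
#' whole-head navigator protocol (128 x 128 x 88 matrix, 256 x 256 x 176 mm
#' field of view).
#'
#' @param shape voxel counts per axis.
#' @param spacing voxel size in mm (scalar or length 3).
#' @param outer_semiaxes_mm,inner_semiaxes_mm semi-axes of the outer and inner
#'   shell ellipsoids in mm; the inner ellipsoid must lie strictly inside the
#'   outer one.
#' @param shell_intensity intensity of shell voxels (arbitrary units).
#' @param blobs list of blobs, each a list with `center_mm` (relative to the
#'   volume centre), `radius_mm`, `intensity`. The defaults place three
#'   asymmetric fat pads so that the phantom has no rotational symmetry.
#' @param noise_sd SD of additive Gaussian noise (>= 0); the noisy image is
#'   rectified (absolute value), mimicking magnitude reconstruction.
#' @param seed integer seed making a phantom reproducible in isolation.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128, 128, 88),
                         spacing = spacing_from_fov(c(256, 256, 176),
                                                    c(128, 128, 88)),
                         outer_semiaxes_mm = NULL,
                         inner_semiaxes_mm = NULL,
                         shell_intensity = 100,
                         blobs = NULL,
                         noise_sd = 5,
                         seed = 1L) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(shape) != 3L || any(shape < 2L)) stop("`shape` must be 3 counts >= 2")
  if (any(spacing <= 0)) stop("`spacing` must be positive")
  fov <- shape * spacing
  if (is.null(outer_semiaxes_mm)) outer_semiaxes_mm <- 0.36 * fov
  if (is.null(inner_semiaxes_mm)) inner_semiaxes_mm <- outer_semiaxes_mm - 0.05 * min(fov)
  if (any(inner_semiaxes_mm <= 0) ||
      any(inner_semiaxes_mm >= outer_semiaxes_mm))
    stop("inner semi-axes must be strictly inside the outer semi-axes")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (is.null(blobs)) {
    r <- 0.08 * min(fov)
    blobs <- list(
      list(center_mm = c(0.05, 0.30, -0.10) * fov, radius_mm = r,
           intensity = 0.8 * shell_intensity),
      list(center_mm = c(-0.22, 0.18, 0.05) * fov, radius_mm = 0.8 * r,
           intensity = 0.7 * shell_intensity),
      list(center_mm = c(0.18, -0.12, 0.20) * fov, radius_mm = 0.7 * r,
           intensity = 0.9 * shell_intensity))
  }
  structure(list(shape = shape, spacing = spacing,
                 outer_semiaxes_mm = outer_semiaxes_mm,
                 inner_semiaxes_mm = inner_semiaxes_mm,
                 shell_intensity = shell_intensity, blobs = blobs,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a fat-navigator-like phantom volume
#'
#' Renders the ellipsoidal scalp-fat shell and blobs described by a
#' [phantom_spec()] and adds rectified Gaussian noise. Deterministic for a
#' fixed spec seed: the same spec always produces a bit-identical volume.
#'
#' @param spec a [phantom_spec()].
#' @return A [volume3d()].
#' @examples
#' vol <- generate_phantom(phantom_spec(shape = c(32, 32, 32), noise_sd = 0))
#' range(vol$data)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape; sp <- spec$spacing
  c_mm <- (d - 1) / 2 * sp
  gx <- ((seq_len(d[1]) - 1) * sp[1] - c_mm[1])
  gy <- ((seq_len(d[2]) - 1) * sp[2] - c_mm[2])
  gz <- ((seq_len(d[3]) - 1) * sp[3] - c_mm[3])
  ex2 <- outer(outer((gx / spec$outer_semiaxes_mm[1])^2,
                     (gy / spec$outer_semiaxes_mm[2])^2, "+"),
               (gz / spec$outer_semiaxes_mm[3])^2, "+")
  in2 <- outer(outer((gx / spec$inner_semiaxes_mm[1])^2,
                     (gy / spec$inner_semiaxes_mm[2])^2, "+"),
               (gz / spec$inner_semiaxes_mm[3])^2, "+")
  vol <- array(0, dim = d)
  vol[ex2 <= 1 & in2 > 1] <- spec$shell_intensity
  for (b in spec$blobs) {
    r2 <- outer(outer((gx - b$center_mm[1])^2, (gy - b$center_mm[2])^2, "+"),
                (gz - b$center_mm[3])^2, "+")
    sel <- r2 <= b$radius_mm^2
    vol[sel] <- pmax(vol[sel], b$intensity)
  }
  if (spec$noise_sd > 0) {
    vol <- withr::with_seed(spec$seed,
                            abs(vol + rnorm(length(vol), 0, spec$noise_sd)))
    dim(vol) <- d
  }
  volume3d(vol, sp)
}

# shift an array by one voxel along an axis (zero fill), used for dilation
shift1 <- function(x, axis, by) {
  d <- dim(x)
  idx <- lapply(d, seq_len)
  src <- idx; dst <- idx
  if (by > 0) { dst[[axis]] <- 2:d[axis]; src[[axis]] <- 1:(d[axis] - 1) }
  else        { dst[[axis]] <- 1:(d[axis] - 1); src[[axis]] <- 2:d[axis] }
  out <- array(0, dim = d)
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

dilate1 <- function(mask) {
  out <- mask
  for (ax in 1:3) for (s in c(-1, 1)) out <- out | shift1(mask, ax, s) > 0
  out
}

#' Estimate background noise statistics of a navigator volume
#'
#' Segments the head by Otsu thresholding, dilates the head mask by one voxel,
#' and returns the mean and SD of the intensities outside it — the values used
#' to fill exposed corners when a transform is applied in image space.
#'
#' @param vol a [volume3d()].
#' @return A list with elements `mean` and `sd`.
#' @export
estimate_background_stats <- function(vol) {
  stopifnot(is_volume3d(vol))
  x <- vol$data
  if (diff(range(x)) == 0)
    stop("volume has no intensity contrast; cannot separate head from background")
  thr <- EBImage::otsu(matrix(as.numeric(x), ncol = 1L),
                       range = range(x), levels = 256L)
  head_mask <- dilate1(x > thr)
  bg <- x[!head_mask]
  if (length(bg) < 2L) stop("no background voxels outside the head mask")
  list(mean = mean(bg), sd = stats::sd(bg))
}
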