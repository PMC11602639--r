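# Image-sharpness quantification used to evaluate motion correction: the
# variance of the image Laplacian (and the corrected/uncorrected ratio), and
# the 75%-to-25% edge-profile width across a dark band such as the cerebral
# falx.

#' Variance of the image Laplacian
#'
#' Convolves a 2D image with the 5-point discrete Laplacian stencil
#' `[[0,1,0],[1,-4,1],[0,1,0]]` over the interior (valid) region and returns
#' the variance of the response. The Laplacian responds to edges, so its
#' variance grows as the image gets crisper; it is exactly 0 for constant and
#' affine-ramp images. For a multi-slice volume pass the slice index; a 3D
#' variant using the 7-point stencil is available as
#' [variance_of_laplacian_3d()].
#'
#' Note the metric is offset-invariant and scales with the *square* of an
#' intensity scaling, and that severe artefacts can inflate it — it is a
#' sharpness proxy, not an artefact detector.
#'
#' @param img 2D matrix (at least 3x3), or a [volume3d()]/3D array with
#'   `slice` given.
#' @param slice slice index along the third axis for 3D input.
#' @return non-negative scalar.
#' @examples
#' variance_of_laplacian(matrix(rep(1:8, 8), 8, 8)) # ramp: 0
#' @export
variance_of_laplacian <- function(img, slice = NULL) {
  img <- metric_data(img)
  if (length(dim(img)) == 3L) {
    if (is.null(slice))
      stop("3D input: give a `slice`, or use variance_of_laplacian_3d()")
    img <- img[, , slice]
  }
  if (!is.matrix(img) || any(dim(img) < 3L))
    stop("`img` must be a 2D image of at least 3x3 pixels")
  n <- nrow(img); m <- ncol(img)
  ci <- 2:(n - 1); cj <- 2:(m - 1)
  lap <- img[ci - 1, cj] + img[ci + 1, cj] + img[ci, cj - 1] +
         img[ci, cj + 1] - 4 * img[ci, cj]
  var(as.numeric(lap))
}

#' @rdname variance_of_laplacian
#' @export
variance_of_laplacian_3d <- function(img) {
  x <- metric_data(img)
  if (length(dim(x)) != 3L || any(dim(x) < 3L))
    stop("`img` must be a 3D array of at least 3 voxels per axis")
  d <- dim(x)
  ci <- 2:(d[1] - 1); cj <- 2:(d[2] - 1); ck <- 2:(d[3] - 1)
  lap <- x[ci - 1, cj, ck] + x[ci + 1, cj, ck] +
         x[ci, cj - 1, ck] + x[ci, cj + 1, ck] +
         x[ci, cj, ck - 1] + x[ci, cj, ck + 1] - 6 * x[ci, cj, ck]
  var(as.numeric(lap))
}

#' Sharpness ratio of corrected to uncorrected images
#'
#' Ratio of the Laplacian variances, `variance_of_laplacian(corrected) /
#' variance_of_laplacian(uncorrected)`. Values above 1 indicate the corrected
#' image is sharper.
#'
#' @param corrected,uncorrected 2D images (or 3D with `slice`).
#' @inheritParams variance_of_laplacian
#' @return positive scalar.
#' @export
sharpness_ratio <- function(corrected, uncorrected, slice = NULL) {
  den <- variance_of_laplacian(uncorrected, slice)
  if (den == 0) stop("degenerate: uncorrected image has zero Laplacian variance")
  variance_of_laplacian(corrected, slice) / den
}

# width of a single monotone flank between plateau (100%) and floor (0%):
# positions where the normalised intensity crosses hi and lo, by linear
# interpolation between samples; `pos` are sample positions in mm
flank_width <- function(vals, pos, hi, lo) {
  top <- max(vals); bot <- min(vals)
  if (top <= bot) return(NA_real_)
  fr <- (vals - bot) / (top - bot)
  cross <- function(level) {
    # first crossing walking from the plateau end toward the floor end
    dir <- if (fr[1] >= fr[length(fr)]) seq_along(fr) else rev(seq_along(fr))
    f <- fr[dir]; p <- pos[dir]
    for (i in seq_len(length(f) - 1)) {
      if ((f[i] - level) * (f[i + 1] - level) <= 0 && f[i] != f[i + 1]) {
        w <- (level - f[i]) / (f[i + 1] - f[i])
        return(p[i] + w * (p[i + 1] - p[i]))
      }
    }
    NA_real_
  }
  abs(cross(lo) - cross(hi))
}

#' Width of an intensity edge from 75% to 25%
#'
#' Quantifies edge steepness on a 1D intensity profile, e.g. a line through
#' the cerebral falx: the profile's dip is located, each flank is normalised
#' between its local plateau (100%) and the dip minimum (0%), and the
#' distance between the 75% and 25% crossings (linear interpolation between
#' samples) is returned in mm. A smaller width means a sharper image. A
#' monotone profile (a single edge) is analysed as one flank.
#'
#' @param profile numeric vector of intensity samples.
#' @param spacing_mm distance between samples in mm.
#' @param hi_frac,lo_frac crossing levels (defaults 0.75 and 0.25).
#' @param both return both flank widths instead of the steeper one.
#' @param plateau_window number of samples on each side of the dip used to
#'   estimate the local plateau (default: all).
#' @return A list of class `profile_width_report`: `width_mm` (steeper
#'   flank), optionally `width_left_mm`/`width_right_mm`, plus the levels and
#'   the input profile.
#' @examples
#' x <- seq(-10, 10, by = 0.05)
#' p <- 1 / (1 + exp(-x / 1.5)) # sigmoid edge, width = 2 * 1.5 * log(3)
#' profile_edge_width(p, spacing_mm = 0.05)$width_mm
#' @export
profile_edge_width <- function(profile, spacing_mm, hi_frac = 0.75,
                               lo_frac = 0.25, both = FALSE,
                               plateau_window = NULL) {
  profile <- as.numeric(profile)
  n <- length(profile)
  if (n < 3L) stop("profile too short")
  if (spacing_mm <= 0) stop("`spacing_mm` must be positive")
  pos <- (seq_len(n) - 1) * spacing_mm

  interior <- 2:(n - 1)
  imin <- interior[which.min(profile[interior])]
  has_dip <- profile[imin] < min(profile[1], profile[n]) - 1e-12 *
    max(1, diff(range(profile)))

  if (has_dip) {
    win <- if (is.null(plateau_window)) n else plateau_window
    li <- max(1L, imin - win):imin
    ri <- imin:min(n, imin + win)
    wl <- flank_width(profile[li], pos[li], hi_frac, lo_frac)
    wr <- flank_width(profile[ri], pos[ri], hi_frac, lo_frac)
    if (all(is.na(c(wl, wr)))) stop("no usable flank around the dip")
    width <- min(wl, wr, na.rm = TRUE)
    out <- list(width_mm = width, width_left_mm = wl, width_right_mm = wr,
                hi_frac = hi_frac, lo_frac = lo_frac,
                profile = profile, spacing_mm = spacing_mm)
  } else {
    dif <- diff(profile)
    if (!(all(dif >= 0) || all(dif <= 0)))
      stop("no dip found and profile is not a monotone edge")
    w <- flank_width(profile, pos, hi_frac, lo_frac)
    if (is.na(w)) stop("profile has no intensity contrast")
    out <- list(width_mm = w, width_left_mm = NA_real_,
                width_right_mm = NA_real_, hi_frac = hi_frac,
                lo_frac = lo_frac, profile = profile, spacing_mm = spacing_mm)
  }
  if (!both) out$profile <- profile
  structure(out, class = "profile_width_report")
}

#' @export
print.profile_width_report <- function(x, ...) {
  cat(sprintf("edge width %.3f mm (%.0f%% -> %.0f%%)\n",
              x$width_mm, 100 * x$hi_frac, 100 * x$lo_frac))
  invisible(x)
}

#' Sample an intensity profile along a line in a slice
#'
#' Linearly interpolates the image along the segment from `(x0, y0)` to
#' `(x1, y1)` (1-based pixel coordinates) at roughly one sample per pixel.
#'
#' @param img 2D matrix or [volume3d()]/3D array with `slice`.
#' @param x0,y0,x1,y1 segment endpoints in pixel coordinates.
#' @param slice slice index for 3D input.
#' @param spacing_mm pixel size in mm (used for the returned positions).
#' @return data frame with columns `pos_mm` and `value`.
#' @export
line_profile <- function(img, x0, y0, x1, y1, slice = NULL, spacing_mm = 1) {
  img <- metric_data(img)
  if (length(dim(img)) == 3L) {
    if (is.null(slice)) stop("3D input: give a `slice`")
    img <- img[, , slice]
  }
  n <- max(2L, ceiling(sqrt((x1 - x0)^2 + (y1 - y0)^2)) + 1L)
  xs <- seq(x0, x1, length.out = n)
  ys <- seq(y0, y1, length.out = n)
  pts <- vapply(seq_len(n), function(i) {
    xi <- xs[i]; yi <- ys[i]
    i0 <- floor(xi); j0 <- floor(yi)
    i0 <- min(max(i0, 1L), nrow(img) - 1L)
    j0 <- min(max(j0, 1L), ncol(img) - 1L)
    fx <- xi - i0; fy <- yi - j0
    img[i0, j0] * (1 - fx) * (1 - fy) + img[i0 + 1, j0] * fx * (1 - fy) +
      img[i0, j0 + 1] * (1 - fx) * fy + img[i0 + 1, j0 + 1] * fx * fy
  }, numeric(1))
  step <- sqrt((xs[2] - xs[1])^2 + (ys[2] - ys[1])^2) * spacing_mm
  data.frame(pos_mm = (seq_len(n) - 1) * step, value = pts)
}
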