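#' 3D image volume with voxel spacing
#'
#' The basic image container: a 3D numeric array plus per-axis voxel size in
#' mm. This is the carrier for navigator images and phantoms. Physical
#' coordinates are voxel-centre coordinates, `(index - 1) * spacing` mm, and
#' the geometric centre of the volume (`(dim - 1) / 2 * spacing`) is the
#' rotation centre used throughout.
#'
#' @param data 3D numeric array of finite intensities. A 2D matrix is promoted
#'   to a single-slice volume.
#' @param spacing numeric vector of 3 positive voxel sizes in mm (a single
#'   value is recycled).
#' @return An object of class `volume3d`: a list with elements `data`,
#'   `spacing` and `shape`.
#' @examples
#' vol <- volume3d(array(0, dim = c(8, 8, 4)), spacing = 2)
#' dim(vol)
#' @export
volume3d <- function(data, spacing = c(1, 1, 1)) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!all(is.finite(data))) stop("volume intensities must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive voxel sizes in mm")
  structure(list(data = data, spacing = spacing, shape = dim(data)),
            class = "volume3d")
}

#' @export
dim.volume3d <- function(x) x$shape

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d> %s voxels, %s mm spacing, range [%.3g, %.3g]\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing, trim = TRUE), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
as.array.volume3d <- function(x, ...) x$data

#' Test for the volume3d class
#' @param x object to test.
#' @return `TRUE` for `volume3d` objects.
#' @export
is_volume3d <- function(x) inherits(x, "volume3d")

# accept either a volume3d or a bare array, returning a volume3d
as_volume3d <- function(x, spacing = c(1, 1, 1)) {
  if (is_volume3d(x)) x else volume3d(x, spacing)
}

#' Voxel spacing implied by a field of view and matrix size
#'
#' @param fov_mm field of view per axis in mm.
#' @param matrix_size acquisition matrix (voxel counts) per axis.
#' @return numeric vector of voxel sizes in mm.
#' @examples
#' spacing_from_fov(c(256, 256, 176), c(128, 128, 88)) # 2 2 2
#' @export
spacing_from_fov <- function(fov_mm, matrix_size) {
  fov_mm <- as.numeric(fov_mm)
  matrix_size <- as.numeric(matrix_size)
  if (length(fov_mm) != length(matrix_size))
    stop("`fov_mm` and `matrix_size` must have the same length")
  if (any(fov_mm <= 0) || any(matrix_size < 1))
    stop("field of view and matrix size must be positive")
  fov_mm / matrix_size
}

#' Read / write a volume as NIfTI-1
#'
#' Voxel spacing is taken from (or written to) the NIfTI header `pixdim`.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns a [volume3d()]; `write_volume` returns `path`
#'   invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(dim(arr), 1L))
  if (length(dim(arr)) > 3L) arr <- array(arr, dim = dim(arr)[1:3])
  volume3d(arr, RNifti::pixdim(img)[1:3])
}

#' @rdname read_volume
#' @param vol a [volume3d()].
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_volume3d(vol))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

# centre of the volume in mm (voxel-centre convention)
volume_center_mm <- function(vol) (vol$shape - 1) / 2 * vol$spacing
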