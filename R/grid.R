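#' Volume grid geometry
#'
#' A `volume_grid` holds the spatial geometry of a 3D sampling grid: its
#' dimensions in voxels, voxel size in mm, and a 4x4 RAS+ affine mapping
#' voxel indices to world (mm) coordinates.  For synthetic grids the origin
#' is placed at the grid centre so that reported coordinates behave like
#' MNI-style millimetre coordinates without requiring registration.
#'
#' Internally voxel indices are 1-based (the R convention); the affine is
#' applied to `index - 1`, so coordinates agree with any 0-based convention.
#'
#' @param dims integer vector of length 3, voxels per axis (all >= 1).
#' @param voxel_size_mm voxel edge length(s) in mm; scalar or length 3.
#' @param affine optional 4x4 voxel-to-mm matrix; default is RAS+, isotropic,
#'   origin at the grid centre.
#' @return An object of class `volume_grid` with fields `dims`,
#'   `voxel_size_mm` and `affine`.
#' @export
#' @examples
#' g <- volume_grid(c(16, 16, 12), 3)
#' voxel_to_mm(g, c(1, 1, 1))   # corner voxel, negative mm coordinates
volume_grid <- function(dims, voxel_size_mm, affine = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L))
    stop("`dims` must be 3 positive integers")
  vs <- rep(as.numeric(voxel_size_mm), length.out = 3L)
  if (any(vs <= 0)) stop("`voxel_size_mm` must be positive")
  if (is.null(affine)) {
    affine <- diag(c(vs, 1))
    affine[1:3, 4] <- -vs * (dims - 1) / 2
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < .Machine$double.eps)
    stop("`affine` must be an invertible 4x4 matrix")
  structure(list(dims = dims, voxel_size_mm = vs, affine = affine),
            class = "volume_grid")
}

#' Convert 1-based voxel indices to mm coordinates
#'
#' @param grid a [volume_grid()].
#' @param ijk numeric vector of length 3 or an n x 3 matrix of 1-based
#'   voxel indices.
#' @return n x 3 matrix (or length-3 vector) of mm coordinates.
#' @export
voxel_to_mm <- function(grid, ijk) {
  one <- is.null(dim(ijk))
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  mm <- cbind(ijk - 1, 1) %*% t(grid$affine)
  mm <- mm[, 1:3, drop = FALSE]
  if (one) drop(mm) else mm
}

#' Convert mm coordinates to nearest 1-based voxel indices
#'
#' @inheritParams voxel_to_mm
#' @param mm length-3 vector or n x 3 matrix of mm coordinates.
#' @return integer voxel indices (1-based), rounded to the nearest voxel.
#' @export
mm_to_voxel <- function(grid, mm) {
  one <- is.null(dim(mm))
  mm <- matrix(as.numeric(mm), ncol = 3L)
  ijk <- cbind(mm, 1) %*% t(solve(grid$affine))
  ijk <- round(ijk[, 1:3, drop = FALSE]) + 1
  storage.mode(ijk) <- "integer"
  if (one) drop(ijk) else ijk
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  invisible(x)
}

#' BOLD time-series volume
#'
#' Container for one subject's 4D BOLD data: a (x, y, z, t) array, the grid
#' geometry, the repetition time, and a 3D logical brain mask.
#'
#' @param data 4D numeric array (x, y, z, t) with t >= 2.
#' @param grid a [volume_grid()] matching the spatial dimensions.
#' @param tr_s repetition time in seconds (> 0).
#' @param mask 3D logical array of the same spatial dimensions; voxels
#'   outside the mask are carried along but ignored by analysis stages.
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(data, grid, tr_s, mask) {
  d <- dim(data)
  if (length(d) != 4L) stop("`data` must be a 4D array (x, y, z, t)")
  if (d[4] < 2L) stop("series needs at least 2 volumes")
  if (!all(d[1:3] == grid$dims)) stop("spatial dims do not match grid")
  if (!is.logical(mask)) mask <- mask > 0
  if (!all(dim(mask) == d[1:3])) stop("mask shape does not match series")
  if (!any(mask)) stop("mask is empty")
  if (!is.numeric(tr_s) || tr_s <= 0) stop("`tr_s` must be positive")
  vals <- data[rep(mask, d[4])]
  if (any(!is.finite(vals))) stop("non-finite values inside mask")
  structure(list(data = data, grid = grid, tr_s = as.numeric(tr_s),
                 mask = mask),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_series> %d x %d x %d x %d (TR %.3g s), %d in-mask voxels\n",
              d[1], d[2], d[3], d[4], x$tr_s, sum(x$mask)))
  invisible(x)
}

#' Number of time points in a series
#' @param series a [bold_series()].
#' @return integer volume count.
#' @export
n_volumes <- function(series) dim(series$data)[4]

# time x voxels matrix of the in-mask (or all-voxel) series
series_matrix <- function(series, mask_only = FALSE) {
  d <- dim(series$data)
  m <- t(matrix(series$data, prod(d[1:3]), d[4]))
  if (mask_only) m[, as.vector(series$mask), drop = FALSE] else m
}

# inverse of series_matrix(mask_only = FALSE)
matrix_to_series <- function(mat, series) {
  d <- dim(series$data)
  series$data <- array(t(mat), dim = d)
  series
}
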