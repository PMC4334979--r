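#' Seed region of interest
#'
#' A set of in-mask voxels used as a connectivity seed, typically the voxels
#' of a surviving cluster from the regional-homogeneity group contrast.
#'
#' @param voxels n x 3 integer matrix of 1-based voxel indices.
#' @param roi_id short identifier.
#' @param source `"reho_cluster"` or `"manual"`.
#' @param label free-text label.
#' @return An object of class `seed_roi`.
#' @export
seed_roi <- function(voxels, roi_id, source = "manual", label = roi_id) {
  voxels <- matrix(as.integer(as.matrix(voxels)), ncol = 3L)
  if (nrow(voxels) == 0L) stop("ROI must contain at least one voxel")
  structure(list(roi_id = as.character(roi_id), voxels = voxels,
                 source = match.arg(source, c("reho_cluster", "manual")),
                 label = as.character(label)),
            class = "seed_roi")
}

#' Spherical ROI from a centre and radius in mm
#'
#' @param grid a [volume_grid()].
#' @param center_mm length-3 centre in mm.
#' @param radius_mm sphere radius in mm.
#' @param mask optional 3D logical array; voxels outside it are dropped.
#' @param roi_id,label identifiers.
#' @return A [seed_roi()].
#' @export
sphere_roi <- function(grid, center_mm, radius_mm, mask = NULL,
                       roi_id = "sphere", label = roi_id) {
  ijk <- arrayInd(seq_len(prod(grid$dims)), grid$dims)
  mm <- voxel_to_mm(grid, ijk)
  inside <- rowSums(sweep(mm, 2L, center_mm)^2) <= radius_mm^2
  if (!is.null(mask)) inside <- inside & as.vector(mask)
  seed_roi(ijk[inside, , drop = FALSE], roi_id, "manual", label)
}

#' Mean time course over an ROI
#'
#' Unweighted average of the voxel series over the ROI at each time point;
#' the standard reference time course for seed-based connectivity.
#'
#' @param series a [bold_series()].
#' @param roi a [seed_roi()] whose voxels lie inside the series mask.
#' @return Numeric vector of length `n_volumes(series)`.
#' @export
roi_mean_timeseries <- function(series, roi) {
  if (nrow(roi$voxels) == 0L) stop("empty ROI")
  lin <- roi$voxels[, 1] +
    dim(series$data)[1] * (roi$voxels[, 2] - 1L) +
    prod(dim(series$data)[1:2]) * (roi$voxels[, 3] - 1L)
  if (!all(series$mask[lin])) stop("ROI contains out-of-mask voxels")
  nt <- n_volumes(series)
  nxyz <- prod(dim(series$data)[1:3])
  m <- matrix(series$data, nxyz, nt)
  colMeans(m[lin, , drop = FALSE])
}

#' Fisher z-transform of correlation coefficients
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`, the variance-stabilising
#' transform used before averaging or testing correlation maps.  Values with
#' `|r| = 1` (e.g. a seed voxel correlated with a single-voxel seed) are
#' clamped to `|r| = 1 - 1e-7` rather than mapped to infinity.
#'
#' @param r correlations, `|r| <= 1` (vector or array; NaN passes through).
#' @return z values of the same shape.
#' @export
#' @examples
#' fisher_z(0.5)    # 0.5493
fisher_z <- function(r) {
  bad <- !is.na(r) & abs(r) > 1
  if (any(bad)) stop("|r| > 1")
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

#' Seed-based voxelwise correlation and Fisher-z map
#'
#' Correlates the ROI mean time course with every in-mask voxel's series
#' (Pearson), then Fisher-z-transforms the result.  Input should already be
#' nuisance-regressed.  Voxels with constant series give NaN; seed voxels
#' are retained in the map.
#'
#' @param series a (preprocessed, nuisance-regressed) [bold_series()].
#' @param roi a [seed_roi()].
#' @return Object of class `connectivity_map` with 3D fields `r_values` and
#'   `z_values` (NaN outside mask), plus `mask`, `grid`, `roi_id`.
#' @export
seed_correlation_map <- function(series, roi) {
  ref <- roi_mean_timeseries(series, roi)
  ref <- ref - mean(ref)
  refn <- sqrt(sum(ref^2))
  if (refn == 0) stop("reference series has zero variance")
  mat <- series_matrix(series, mask_only = TRUE)
  mat <- sweep(mat, 2L, colMeans(mat))
  vn <- sqrt(colSums(mat^2))
  r <- as.vector(crossprod(mat, ref)) / (vn * refn)   # 0/0 -> NaN for flat voxels
  r <- pmin(pmax(r, -1), 1)
  rv <- array(NaN, dim = series$grid$dims)
  rv[series$mask] <- r
  zv <- array(NaN, dim = series$grid$dims)
  zv[series$mask] <- fisher_z(r)
  structure(list(roi_id = roi$roi_id, r_values = rv, z_values = zv,
                 mask = series$mask, grid = series$grid),
            class = "connectivity_map")
}

#' @export
print.connectivity_map <- function(x, ...) {
  cat(sprintf("<connectivity_map> seed '%s', %s, in-mask mean z %.4f\n",
              x$roi_id, paste(x$grid$dims, collapse = "x"),
              mean(x$z_values[x$mask], na.rm = TRUE)))
  invisible(x)
}
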