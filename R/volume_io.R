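#' Load a 4D BOLD series and its brain mask from NIfTI-1 files
#'
#' Grid geometry (dimensions, voxel size, affine) is taken from the series
#' header; the repetition time is read from the header's 4th pixdim unless
#' overridden.
#'
#' @param path path to a 4D NIfTI-1 file (.nii or .nii.gz).
#' @param mask_path path to a 3D NIfTI-1 mask with matching spatial shape;
#'   nonzero voxels are in-mask.
#' @param tr_s optional repetition time in seconds; defaults to the header
#'   value.
#' @return A [bold_series()].
#' @export
load_series <- function(path, mask_path, tr_s = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(mask_path)) stop("no such file: ", mask_path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("expected a 4D series, got ", length(d), "D image: ", path)
  msk <- RNifti::readNifti(mask_path)
  if (length(dim(msk)) != 3L)
    stop("mask must be a 3D image: ", mask_path)
  if (!all(dim(msk) == d[1:3]))
    stop("mask dims (", paste(dim(msk), collapse = "x"),
         ") do not match series spatial dims (",
         paste(d[1:3], collapse = "x"), ")")
  pd <- RNifti::pixdim(img)
  if (is.null(tr_s)) tr_s <- if (length(pd) >= 4L && pd[4] > 0) pd[4] else 1
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  grid <- volume_grid(d[1:3], pd[1:3], affine = matrix(aff, 4, 4))
  bold_series(array(as.numeric(img), dim = d), grid, tr_s,
              array(as.numeric(msk) > 0, dim = d[1:3]))
}

# attach grid geometry to an array and write it
write_nifti_grid <- function(arr, grid, path, tr_s = NULL) {
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  pd <- grid$voxel_size_mm
  if (nd == 4L) pd <- c(pd, if (is.null(tr_s)) 1 else tr_s)
  RNifti::pixdim(img) <- pd
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Save a 3D map (or 4D series) as NIfTI-1 with the grid's affine
#'
#' Values are stored at double precision; NaN (e.g. outside-mask voxels)
#' round-trip unchanged.
#'
#' @param field3d 3D (or 4D) numeric array whose spatial dims match `grid`.
#' @param grid a [volume_grid()].
#' @param path output path (.nii or .nii.gz).
#' @param tr_s repetition time stored in the 4th pixdim for 4D arrays.
#' @return `path`, invisibly.
#' @export
save_map <- function(field3d, grid, path, tr_s = NULL) {
  d <- dim(field3d)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("`field3d` must be a 3D or 4D array")
  if (!all(d[1:3] == grid$dims)) stop("field dims do not match grid")
  write_nifti_grid(field3d, grid, path, tr_s)
}

#' Read a rigid-motion parameter file
#'
#' Expects whitespace-separated text with exactly 6 numeric columns, one row
#' per volume: 3 translations (mm) then 3 rotations (degrees).
#'
#' @param path path to the motion file.
#' @return A tibble with columns `trans_x`, `trans_y`, `trans_z` (mm) and
#'   `rot_x`, `rot_y`, `rot_z` (degrees), one row per volume.
#' @export
read_motion_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, header = FALSE)
  if (ncol(tab) != 6L)
    stop("motion file must have 6 columns, found ", ncol(tab), ": ", path)
  names(tab) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  tibble::as_tibble(tab)
}

write_motion_params <- function(motion, path) {
  utils::write.table(format(as.data.frame(motion), digits = 17,
                            scientific = TRUE, trim = TRUE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a cluster table as TSV
#'
#' Mirrors the usual published cluster-report layout: one row per cluster
#' with its peak coordinate in mm, peak t score and extent in voxels.
#'
#' @param clusters a cluster table as returned by [extract_clusters()]
#'   (columns `cluster_id`, `x_mm`, `y_mm`, `z_mm`, `peak_t`, `n_voxels`
#'   are used).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(clusters, path) {
  cols <- c("cluster_id", "x_mm", "y_mm", "z_mm", "peak_t", "n_voxels")
  df <- as.data.frame(clusters)[, intersect(cols, names(clusters)), drop = FALSE]
  if (nrow(df) == 0L)
    df <- stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(cols))),
                          cols)
  names(df)[names(df) == "cluster_id"] <- "region_id"
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
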