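#' Build a group design matrix with nuisance covariates
#'
#' Columns: intercept, group indicator (patient = 1), then the requested
#' covariates (sex coded 0/1).  The associated contrast picks out the group
#' column, realising the covariate-adjusted two-sample t-test as a GLM
#' contrast.
#'
#' @param subjects subject table (tibble/data.frame) with a `group` column
#'   (`"patient"`/`"control"`) and the covariate columns.
#' @param covariates character vector of covariate column names; default the
#'   conventional four (age, sex, education, gray-matter volume).
#' @return List with `X` (matrix), `contrast` (vector), `columns`.
#' @export
make_design <- function(subjects,
                        covariates = c("age_years", "sex", "education_years",
                                       "gm_volume_ml")) {
  subjects <- as.data.frame(subjects)
  grp <- as.integer(subjects$group == "patient")
  X <- cbind(intercept = 1, group = grp)
  for (cv in covariates) {
    v <- subjects[[cv]]
    if (is.null(v)) stop("missing covariate column: ", cv)
    if (is.character(v) || is.factor(v))
      v <- as.integer(factor(v)) - 1L   # e.g. sex female/male -> 0/1
    X <- cbind(X, v)
  }
  colnames(X) <- c("intercept", "group", covariates)
  contrast <- c(0, 1, rep(0, length(covariates)))
  list(X = X, contrast = contrast, columns = colnames(X))
}

#' Voxelwise GLM contrast t-map
#'
#' Fits, at every in-mask voxel, ordinary least squares of the per-subject
#' map values on the design matrix and forms
#' `t = c'beta / sqrt(sigma^2 c'(X'X)^{-1} c)` with `dof = n - p`.  With a
#' design of intercept + group indicator and the group contrast this equals
#' the classical pooled two-sample t-test; adding covariate columns gives
#' the covariate-adjusted group comparison.  An intercept-only design with
#' contrast 1 is the one-sample t-test.  Residual maps are retained for
#' smoothness estimation.
#'
#' @param maps 4D array (x, y, z, subject) of per-subject maps, or a list of
#'   3D arrays in subject order.
#' @param design design matrix (subjects x p), or the list from
#'   [make_design()].
#' @param contrast contrast vector of length p (ignored if `design` comes
#'   from [make_design()], which carries its own).
#' @param mask 3D logical array.
#' @param grid a [volume_grid()].
#' @return Object of class `stat_map`: `t_values` (3D, NaN outside mask),
#'   `dof`, `residuals` (4D), `mask`, `grid`.  Voxels with zero residual
#'   variance get t = 0 when the contrast estimate is 0 and +/-Inf otherwise.
#' @export
glm_contrast_tmap <- function(maps, design, contrast = NULL, mask, grid) {
  if (is.list(design) && !is.null(design$X)) {
    if (is.null(contrast)) contrast <- design$contrast
    design <- design$X
  }
  X <- as.matrix(design)
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(contrast)) stop("contrast required")
  if (length(contrast) != p) stop("contrast length must equal design columns")
  if (n <= p) stop("fewer subjects than design columns + 1")
  qrx <- qr(X)
  if (qrx$rank < p) stop("rank-deficient design")
  if (is.list(maps)) maps <- array(unlist(maps), dim = c(grid$dims, length(maps)))
  if (dim(maps)[4] != n) stop("subject count mismatch between maps and design")

  mvec <- as.vector(mask)
  Y <- matrix(maps, ncol = n)[mvec, , drop = FALSE]   # voxels x subjects
  Y <- t(Y)                                           # subjects x voxels
  beta <- qr.coef(qrx, Y)
  res <- qr.resid(qrx, Y)
  dof <- n - p
  sigma2 <- colSums(res^2) / dof
  XtXinv <- chol2inv(qr.R(qrx))
  cvar <- drop(t(contrast) %*% XtXinv %*% contrast)
  num <- drop(crossprod(contrast, beta))
  # variance at rounding-noise level counts as degenerate (constant maps)
  zerovar <- sigma2 <= .Machine$double.eps * colMeans(Y^2)
  se <- sqrt(sigma2 * cvar)
  tv <- ifelse(se > 0 & !zerovar, num / se,
               ifelse(abs(num) <= sqrt(.Machine$double.eps), 0,
                      sign(num) * Inf))
  if (any(!is.finite(tv)))
    warning("degenerate zero-variance voxels produced infinite t values")

  t3 <- array(NaN, dim = grid$dims)
  t3[mvec] <- tv
  resid4 <- array(NaN, dim = c(grid$dims, n))
  rm4 <- matrix(resid4, ncol = n)
  rm4[mvec, ] <- t(res)
  resid4 <- array(rm4, dim = c(grid$dims, n))
  structure(list(t_values = t3, dof = dof, residuals = resid4,
                 mask = mask, grid = grid, contrast = contrast),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  tv <- x$t_values[x$mask]
  cat(sprintf("<stat_map> %s, dof %d, t range [%.3f, %.3f]\n",
              paste(x$grid$dims, collapse = "x"), x$dof,
              min(tv), max(tv)))
  invisible(x)
}

#' Extract supra-threshold clusters from a t-map
#'
#' Thresholds the t-field at the voxelwise `p_voxel` quantile of t(dof)
#' (two-sided by default), labels connected components of each sign
#' separately, drops components smaller than `min_extent`, and reports each
#' surviving cluster's extent and peak.
#'
#' @param stat a `stat_map` from [glm_contrast_tmap()].
#' @param p_voxel voxelwise threshold probability (default 0.01).
#' @param min_extent minimum cluster size in voxels (e.g. from
#'   [alphasim_min_extent()]; default 1).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param sided `"two"` (default) or `"one"` (positive tail only).
#' @return A tibble with columns `cluster_id`, `sign`, `n_voxels`, `peak_t`,
#'   `x_mm`, `y_mm`, `z_mm` and a list-column `voxels` of n x 3 index
#'   matrices; empty tibble when nothing survives.
#' @export
extract_clusters <- function(stat, p_voxel = 0.01, min_extent = 1L,
                             connectivity = 26L, sided = c("two", "one")) {
  sided <- match.arg(sided)
  tc <- if (sided == "two") stats::qt(1 - p_voxel / 2, stat$dof) else
    stats::qt(1 - p_voxel, stat$dof)
  tv <- stat$t_values
  tv[!stat$mask] <- 0
  tv[is.na(tv)] <- 0
  empty <- tibble::tibble(cluster_id = integer(), sign = character(),
                          n_voxels = integer(), peak_t = numeric(),
                          x_mm = numeric(), y_mm = numeric(), z_mm = numeric(),
                          voxels = list())
  rows <- list()
  signs <- if (sided == "two") c("positive", "negative") else "positive"
  for (sgn in signs) {
    flags <- if (sgn == "positive") tv > tc else tv < -tc
    if (!any(flags)) next
    lab <- label_clusters(flags, connectivity)
    for (k in seq_along(lab$sizes)) {
      if (lab$sizes[k] < min_extent) next
      vox_lin <- which(lab$labels == k)
      vals <- stat$t_values[vox_lin]
      pk <- vox_lin[which.max(abs(vals))]
      pk_mm <- voxel_to_mm(stat$grid, arrayInd(pk, stat$grid$dims))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        cluster_id = NA_integer_, sign = sgn,
        n_voxels = lab$sizes[k], peak_t = vals[which.max(abs(vals))],
        x_mm = pk_mm[1], y_mm = pk_mm[2], z_mm = pk_mm[3],
        voxels = list(arrayInd(vox_lin, stat$grid$dims)))
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_voxels), ]
  out$cluster_id <- seq_len(nrow(out))
  out
}

#' Turn positive clusters into connectivity seeds
#'
#' One [seed_roi()] per positive-sign cluster (the regions of increased
#' local synchrony in the group contrast), in cluster-table order.
#'
#' @param clusters cluster table from [extract_clusters()].
#' @param sign which sign to convert (default `"positive"`).
#' @return List of [seed_roi()]; empty (with a warning) when no cluster of
#'   the requested sign exists.
#' @export
seeds_from_clusters <- function(clusters, sign = "positive") {
  sel <- which(clusters$sign == sign)
  if (!length(sel)) {
    warning("no ", sign, " clusters; returning empty seed list")
    return(list())
  }
  lapply(sel, function(i)
    seed_roi(clusters$voxels[[i]], roi_id = paste0("seed_", clusters$cluster_id[i]),
             source = "reho_cluster",
             label = sprintf("%s cluster %d (%d voxels)", sign,
                             clusters$cluster_id[i], clusters$n_voxels[i])))
}

#' Combine per-group one-sample significance into a test mask
#'
#' Union of the voxels belonging to surviving clusters of each group's
#' one-sample connectivity test; the two-sample contrast for a seed is then
#' restricted to this mask.
#'
#' @param stat_a,stat_b one-sample `stat_map`s for the two groups.
#' @param p_voxel,min_extent,connectivity,sided thresholding settings passed
#'   to [extract_clusters()].
#' @return 3D logical array (empty, with a warning, when neither group shows
#'   significant connectivity).
#' @export
build_connectivity_mask <- function(stat_a, stat_b, p_voxel = 0.01,
                                    min_extent = 1L, connectivity = 26L,
                                    sided = "two") {
  out <- array(FALSE, dim = stat_a$grid$dims)
  for (st in list(stat_a, stat_b)) {
    cl <- extract_clusters(st, p_voxel, min_extent, connectivity, sided)
    for (v in cl$voxels) out[v] <- TRUE
  }
  if (!any(out)) warning("no significant connectivity in either group")
  out
}
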