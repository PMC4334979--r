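#' Kendall's coefficient of concordance (W)
#'
#' Measures agreement among K time series over n time points on the rank
#' scale.  Each series is ranked over time (midranks for ties); with rank
#' sums \eqn{R_i} across series at each time point,
#' \deqn{W = \frac{\sum_i R_i^2 - n \bar R^2}{K^2 (n^3 - n)/12 - K \sum T / 12}}
#' where \eqn{\sum T} is the usual tie-correction term
#' \eqn{\sum_j \sum_g (t_{jg}^3 - t_{jg})} over tie groups of each series
#' (omitted when `tie_correct = FALSE`, mirroring legacy implementations).
#' W is 1 when all series share one rank ordering and has expectation 1/K
#' for independent series.  If every series is constant the rank variance is
#' undefined and 0 is returned.
#'
#' @param block K x n numeric matrix: K series (rows) over n time points.
#' @param tie_correct subtract the tie-correction term from the denominator
#'   (default TRUE).
#' @return W in `[0, 1]`.
#' @export
#' @examples
#' kendall_w(rbind(1:5, 1:5, 1:5))          # 1: perfect concordance
#' kendall_w(rbind(1:3, 3:1))               # 0: perfect discordance
kendall_w <- function(block, tie_correct = TRUE) {
  block <- as.matrix(block)
  K <- nrow(block)
  n <- ncol(block)
  if (K < 2L) stop("need at least 2 series")
  if (n < 2L) stop("need at least 2 time points")
  ranks <- t(apply(block, 1L, rank))
  R <- colSums(ranks)
  S <- sum(R^2) - n * mean(R)^2
  Tsum <- if (tie_correct) {
    sum(apply(block, 1L, function(x) {
      t <- table(x)
      sum(t^3 - t)
    }))
  } else 0
  denom <- (K^2 * (n^3 - n) - K * Tsum) / 12
  if (denom <= 0) return(0)
  min(max(S / denom, 0), 1)
}

# neighbourhood offsets: 7 = faces, 19 = faces+edges, 27 = full cube
# (includes the centre voxel itself)
neighbourhood_offsets <- function(neighbourhood = 27L) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(g))
  keep <- switch(as.character(neighbourhood),
                 "7"  = ord <= 1,
                 "19" = ord <= 2,
                 "27" = rep(TRUE, nrow(g)),
                 stop("neighbourhood must be 7, 19 or 27"))
  g[keep, , drop = FALSE]
}

#' Voxelwise regional homogeneity (ReHo) map
#'
#' Computes Kendall's W over each in-mask voxel's time series together with
#' its in-mask neighbours (26 nearest neighbours for the default 27-voxel
#' cube) and assigns the value to the central voxel.  Neighbours falling
#' outside the mask are dropped, so K adapts near the brain edge; a voxel
#' with no in-mask neighbour (K < 2) gets NaN.  Intended input is a
#' detrended, band-pass-filtered, unsmoothed series.
#'
#' @param series a [bold_series()].
#' @param neighbourhood 7, 19 or 27 (cube including the centre; default 27).
#' @param tie_correct see [kendall_w()].
#' @return An object of class `reho_map`: fields `values` (3D, NaN outside
#'   mask), `mask`, `grid`, `neighbourhood`, `normalized`.
#' @export
reho_map <- function(series, neighbourhood = 27L, tie_correct = TRUE) {
  mask <- series$mask
  if (!any(mask)) stop("empty mask")
  d <- dim(series$data)
  nt <- d[4]
  vox <- which(mask)                       # linear indices of in-mask voxels
  V <- length(vox)
  id_of <- array(0L, dim = d[1:3])
  id_of[vox] <- seq_len(V)
  coords <- arrayInd(vox, d[1:3])

  mat <- series_matrix(series, mask_only = TRUE)   # nt x V
  ranks <- matrix(0, nt, V)
  tie_T <- numeric(V)
  for (v in seq_len(V)) {
    r <- rank(mat[, v])
    ranks[, v] <- r
    if (tie_correct && anyDuplicated(r)) {
      t <- tabulate(match(r, unique(r)))
      t <- t[t > 1L]
      tie_T[v] <- sum(t^3 - t)
    }
  }

  offs <- neighbourhood_offsets(neighbourhood)
  dm <- d[1:3]
  nbr <- matrix(0L, nrow(offs), V)
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2L, offs[o, ], "+")
    ok <- nb[, 1] >= 1L & nb[, 1] <= dm[1] &
          nb[, 2] >= 1L & nb[, 2] <= dm[2] &
          nb[, 3] >= 1L & nb[, 3] <= dm[3]
    nbr[o, ok] <- id_of[nb[ok, , drop = FALSE]]
  }
  W <- reho_kernel(ranks, tie_T, nbr)
  vals <- array(NaN, dim = dm)
  vals[vox] <- W
  structure(list(values = vals, mask = mask, grid = series$grid,
                 neighbourhood = as.integer(neighbourhood),
                 normalized = FALSE),
            class = "reho_map")
}

#' Normalize a ReHo map by its global (in-mask) mean
#'
#' Divides every in-mask value by the in-mask mean, so the normalised map
#' has in-mask mean exactly 1; the result is invariant to rescaling of the
#' input.
#'
#' @param map a `reho_map` (or any list with `values` and `mask`).
#' @return The normalised `reho_map` with `normalized = TRUE`.
#' @export
normalize_global_mean <- function(map) {
  mu <- mean(map$values[map$mask])
  if (!is.finite(mu) || mu <= 0) stop("in-mask mean must be positive")
  map$values[map$mask] <- map$values[map$mask] / mu
  map$normalized <- TRUE
  map
}

#' Smooth a ReHo (or any 3D statistic) map within its mask
#'
#' Mask-normalised Gaussian smoothing of the map values; see
#' [spatial_smooth()].
#'
#' @param map a `reho_map`.
#' @param fwhm_mm kernel FWHM in mm.
#' @return The smoothed map.
#' @export
smooth_map <- function(map, fwhm_mm = 4) {
  map$values <- spatial_smooth(map$values, fwhm_mm, map$grid, map$mask)
  map
}

#' @export
print.reho_map <- function(x, ...) {
  cat(sprintf("<reho_map> %s, %d-voxel neighbourhood, in-mask mean %.4f%s\n",
              paste(x$grid$dims, collapse = "x"), x$neighbourhood,
              mean(x$values[x$mask]),
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}
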