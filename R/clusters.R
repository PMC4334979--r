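#' Neighbour offsets for a 3D connectivity scheme
#'
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (full cube,
#'   excluding the centre).
#' @return m x 3 integer matrix of offsets.
#' @export
connectivity_offsets <- function(connectivity = 26L) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
                 "6"  = rowSums(abs(g)) == 1,
                 "18" = rowSums(abs(g)) <= 2,
                 "26" = rep(TRUE, nrow(g)),
                 stop("connectivity must be 6, 18 or 26"))
  g[keep, , drop = FALSE]
}

#' Label connected components of a 3D logical array
#'
#' Breadth-first labelling under the chosen neighbour connectivity.
#'
#' @param flags 3D logical array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return List with `labels` (3D integer array, 0 = background) and
#'   `sizes` (integer vector, one entry per component).
#' @export
label_clusters <- function(flags, connectivity = 26L) {
  d <- dim(flags)
  labels <- array(0L, dim = d)
  idx <- which(flags)
  if (length(idx) == 0L) return(list(labels = labels, sizes = integer(0)))
  offs <- connectivity_offsets(connectivity)
  no <- nrow(offs)
  sizes <- integer(0)
  lab <- 0L
  for (seed in idx) {
    if (labels[seed] != 0L) next
    lab <- lab + 1L
    labels[seed] <- lab
    queue <- seed
    size <- 1L
    while (length(queue)) {
      cur <- queue[1L]
      queue <- queue[-1L]
      cc <- arrayInd(cur, d)
      for (o in seq_len(no)) {
        x <- cc[1L] + offs[o, 1L]
        y <- cc[2L] + offs[o, 2L]
        z <- cc[3L] + offs[o, 3L]
        if (x < 1L || x > d[1L] || y < 1L || y > d[2L] ||
            z < 1L || z > d[3L]) next
        li <- x + d[1L] * (y - 1L) + d[1L] * d[2L] * (z - 1L)
        if (flags[li] && labels[li] == 0L) {
          labels[li] <- lab
          queue <- c(queue, li)
          size <- size + 1L
        }
      }
    }
    sizes <- c(sizes, size)
  }
  list(labels = labels, sizes = sizes)
}

#' Estimate spatial smoothness (FWHM) from residual maps
#'
#' Gaussian-random-field estimator: each residual map is standardised to
#' unit in-mask variance; for each axis the variance of first spatial
#' differences between in-mask neighbour pairs gives the lag-one
#' autocorrelation `rho = 1 - var(diff) / 2`, and under a Gaussian
#' autocorrelation function the kernel width follows from
#' `sigma^2 = -d^2 / (4 log rho)` (d = voxel size).  Estimates are pooled
#' over maps; a non-positive `rho` yields 0 for that axis.
#'
#' @param residual_maps 4D array (x, y, z, map) of residuals, or a list of
#'   3D arrays; at least 2 maps.
#' @param grid a [volume_grid()].
#' @param mask 3D logical array.
#' @return List of class `smoothness_estimate` with `fwhm_mm` (length 3).
#' @export
estimate_fwhm <- function(residual_maps, grid, mask) {
  if (is.list(residual_maps))
    residual_maps <- array(unlist(residual_maps),
                           dim = c(grid$dims, length(residual_maps)))
  d <- dim(residual_maps)
  if (length(d) != 4L || d[4] < 2L) stop("need >= 2 residual maps")
  m <- as.vector(mask)
  nmap <- d[4]
  ssd <- numeric(3)   # pooled sum of squared neighbour differences
  npair <- numeric(3)
  svar <- 0           # pooled sum of squares of standardised values
  nval <- 0
  # neighbour-pair index pairs per axis, computed once on the mask
  lin <- which(mask)
  cc <- arrayInd(lin, grid$dims)
  pair_idx <- vector("list", 3)
  for (ax in 1:3) {
    nb <- cc
    nb[, ax] <- nb[, ax] + 1L
    ok <- nb[, ax] <= grid$dims[ax]
    nbl <- nb[ok, 1] + grid$dims[1] * (nb[ok, 2] - 1L) +
      prod(grid$dims[1:2]) * (nb[ok, 3] - 1L)
    keep <- mask[nbl]
    pair_idx[[ax]] <- cbind(lin[ok][keep], nbl[keep])
  }
  for (j in seq_len(nmap)) {
    v <- residual_maps[, , , j]
    vals <- v[m]
    s <- stats::sd(vals)
    if (!is.finite(s) || s == 0) stop("constant residual map")
    v <- v / s
    svar <- svar + sum((v[m] - mean(v[m]))^2)
    nval <- nval + sum(m)
    for (ax in 1:3) {
      p <- pair_idx[[ax]]
      dd <- v[p[, 1]] - v[p[, 2]]
      ssd[ax] <- ssd[ax] + sum(dd^2)
      npair[ax] <- npair[ax] + nrow(p)
    }
  }
  vtot <- svar / nval
  fwhm <- numeric(3)
  for (ax in 1:3) {
    rho <- 1 - (ssd[ax] / npair[ax]) / (2 * vtot)
    fwhm[ax] <- if (rho <= 0) 0 else {
      sigma2 <- -grid$voxel_size_mm[ax]^2 / (4 * log(rho))
      2 * sqrt(2 * log(2)) * sqrt(sigma2)
    }
  }
  structure(list(fwhm_mm = fwhm), class = "smoothness_estimate")
}

#' Monte-Carlo cluster-extent threshold (AlphaSim-style)
#'
#' Repeatedly simulates a standard-normal field on the mask's bounding box,
#' smooths it to the target FWHM, standardises within the mask, thresholds
#' at the voxelwise p, and records the largest supra-threshold cluster.  The
#' returned minimum extent is the smallest cluster size whose family-wise
#' occurrence probability across iterations is at most `alpha`.
#'
#' @param mask 3D logical array.
#' @param grid a [volume_grid()].
#' @param fwhm_mm target field smoothness (scalar or per-axis, mm); use the
#'   estimate from [estimate_fwhm()] on the analysis residuals.
#' @param p_voxel voxelwise threshold probability (default 0.01).
#' @param alpha cluster-wise family error target (default 0.05).
#' @param sided `"two"` thresholds `|z|`, `"one"` thresholds `z` (default two).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param n_iterations Monte-Carlo iterations (default 1000).
#' @param rng_seed integer seed; the result is deterministic given the seed.
#' @return Integer minimum cluster extent (voxels), with attribute
#'   `max_sizes` holding the per-iteration largest-cluster sizes.
#' @export
alphasim_min_extent <- function(mask, grid, fwhm_mm, p_voxel = 0.01,
                                alpha = 0.05, sided = c("two", "one"),
                                connectivity = 26L, n_iterations = 1000L,
                                rng_seed = 1L) {
  sided <- match.arg(sided)
  if (!any(mask)) stop("empty mask")
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]")
  if (!(p_voxel > 0 && p_voxel < 1)) stop("p_voxel must be in (0, 1)")
  if (alpha >= 1) return(structure(1L, max_sizes = integer(0)))
  fw <- rep(as.numeric(fwhm_mm), length.out = 3L)
  zc <- if (sided == "two") stats::qnorm(1 - p_voxel / 2) else
    stats::qnorm(1 - p_voxel)

  # bounding box of the mask
  cc <- arrayInd(which(mask), dim(mask))
  lo <- apply(cc, 2, min)
  hi <- apply(cc, 2, max)
  bd <- hi - lo + 1L
  bmask <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  dim(bmask) <- bd
  bgrid <- volume_grid(bd, grid$voxel_size_mm)
  sig <- fw / (2 * sqrt(2 * log(2))) / grid$voxel_size_mm
  mvec <- as.vector(bmask)
  nin <- sum(mvec)

  max_sizes <- integer(n_iterations)
  with_local_seed(rng_seed, {
    chunk <- 64L
    done <- 0L
    while (done < n_iterations) {
      nb <- min(chunk, n_iterations - done)
      fields <- array(stats::rnorm(prod(bd) * nb), dim = c(bd, nb))
      if (any(sig > 0)) fields <- smooth_stack(fields, sig)
      fm <- matrix(fields, ncol = nb)[mvec, , drop = FALSE]
      if (nin > 1L) {
        mu <- colMeans(fm)
        sdv <- sqrt(colSums(sweep(fm, 2L, mu)^2) / (nin - 1))
      } else {
        # a single-voxel mask cannot be standardised internally; unsmoothed
        # fields are already standard normal
        mu <- rep(0, nb)
        sdv <- rep(1, nb)
      }
      for (b in seq_len(nb)) {
        zin <- (fm[, b] - mu[b]) / sdv[b]
        supra <- if (sided == "two") abs(zin) > zc else zin > zc
        if (!any(supra)) { max_sizes[done + b] <- 0L; next }
        flags <- array(FALSE, dim = bd)
        flags[mvec][supra] <- TRUE
        sz <- label_clusters(flags, connectivity)$sizes
        max_sizes[done + b] <- max(sz)
      }
      done <- done + nb
    }
  })
  smax <- max(max_sizes, 0L)
  ext <- smax + 1L
  for (s in seq_len(smax + 1L)) {
    if (mean(max_sizes >= s) <= alpha) { ext <- s; break }
  }
  structure(as.integer(ext), max_sizes = max_sizes)
}

# run expr with a temporary RNG state seeded by `seed`
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}
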