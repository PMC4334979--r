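# shared fixtures: small synthetic series and cohorts, built in code

# deterministic random bold_series on a small grid
make_random_series <- function(dims = c(8, 8, 6), nt = 40, tr_s = 2,
                               seed = 1, mask = NULL) {
  set.seed(seed)
  grid <- volume_grid(dims, 3)
  if (is.null(mask)) mask <- array(TRUE, dim = dims)
  data <- array(rnorm(prod(dims) * nt), dim = c(dims, nt))
  bold_series(data, grid, tr_s, mask)
}

# reduced-grid cohort spec used by integration-style tests; spheres sit
# inside the ellipsoidal mask of the 16 x 16 x 12 grid
small_cohort_spec <- function(n_a = 4, n_b = 4, n_volumes = 120, seed = 1,
                              local_a = 0.5, local_b = 0.25,
                              slope = 0.8, slope_b = 0.4 * slope, ...) {
  cohort_spec(
    n_group_a = n_a, n_group_b = n_b, grid_dims = c(16, 16, 12),
    mask_radius_mm = 21, n_volumes = n_volumes,
    planted_effects = list(planted_effect(
      center_mm = c(-7.5, 4.5, 1.5), radius_mm = 9,
      local_coupling_a = local_a, local_coupling_b = local_b,
      remote_center_mm = c(7.5, -7.5, 1.5), remote_radius_mm = 9,
      connectivity_slope = slope, connectivity_slope_b = slope_b)),
    rng_seed = seed, ...)
}

# linear indices of an n x 3 voxel index matrix
lin_index <- function(vox, dims) {
  vox[, 1] + dims[1] * (vox[, 2] - 1L) + dims[1] * dims[2] * (vox[, 3] - 1L)
}

# independent brute-force Kendall W oracle: textbook rank-sum definition
# evaluated with explicit loops (midranks; tie term per series)
oracle_kendall_w <- function(block, tie_correct = TRUE) {
  K <- nrow(block)
  n <- ncol(block)
  ranks <- matrix(0, K, n)
  for (j in 1:K) ranks[j, ] <- rank(block[j, ])
  R <- numeric(n)
  for (i in 1:n) for (j in 1:K) R[i] <- R[i] + ranks[j, i]
  Rbar <- mean(R)
  S <- 0
  for (i in 1:n) S <- S + (R[i] - Rbar)^2
  Tsum <- 0
  if (tie_correct) {
    for (j in 1:K) {
      for (v in unique(block[j, ])) {
        t <- sum(block[j, ] == v)
        if (t > 1) Tsum <- Tsum + (t^3 - t)
      }
    }
  }
  denom <- (K^2 * (n^3 - n) - K * Tsum) / 12
  if (denom <= 0) 0 else S / denom
}
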