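test_that("glm_contrast_tmap equals the classical pooled two-sample t", {
  grid <- volume_grid(c(5, 5, 4), 3)
  mask <- array(TRUE, c(5, 5, 4))
  set.seed(19)
  n1 <- 8; n2 <- 9
  maps <- array(rnorm(prod(grid$dims) * (n1 + n2)), c(grid$dims, n1 + n2))
  X <- cbind(1, rep(c(1, 0), c(n1, n2)))
  st <- glm_contrast_tmap(maps, X, contrast = c(0, 1), mask = mask, grid = grid)
  expect_equal(st$dof, n1 + n2 - 2)
  # independent oracle: t.test with pooled variance, voxel by voxel
  for (v in list(c(1, 1, 1), c(3, 4, 2), c(5, 5, 4))) {
    y <- maps[v[1], v[2], v[3], ]
    tt <- t.test(y[1:n1], y[(n1 + 1):(n1 + n2)], var.equal = TRUE)
    expect_equal(st$t_values[v[1], v[2], v[3]], unname(tt$statistic),
                 tolerance = 1e-10)
  }
  # identical groups -> t = 0 everywhere
  same <- maps
  same[, , , (n1 + 1):(n1 + n2)] <- 0
  same[, , , 1:n1] <- 0
  st0 <- glm_contrast_tmap(same, X, contrast = c(0, 1), mask = mask,
                           grid = grid)
  expect_true(all(st0$t_values[mask] == 0))
})

test_that("worked pooled-t example: {1,2,3} vs {3,4,5}", {
  grid <- volume_grid(c(3, 3, 3), 3)
  mask <- array(TRUE, c(3, 3, 3))
  maps <- array(rep(c(1, 2, 3, 3, 4, 5), each = 27), c(3, 3, 3, 6))
  X <- cbind(1, c(1, 1, 1, 0, 0, 0))
  st <- glm_contrast_tmap(maps, X, contrast = c(0, 1), mask = mask, grid = grid)
  expect_equal(abs(st$t_values[2, 2, 2]), 2.449, tolerance = 1e-3)
  expect_equal(st$dof, 4)
})

test_that("covariate adjustment matches lm() per voxel", {
  grid <- volume_grid(c(4, 4, 3), 3)
  mask <- array(TRUE, c(4, 4, 3))
  set.seed(29)
  n <- 20
  subjects <- tibble::tibble(
    group = rep(c("patient", "control"), each = n / 2),
    age_years = rnorm(n, 45, 10), sex = sample(c("male", "female"), n, TRUE),
    education_years = rnorm(n, 11, 2), gm_volume_ml = rnorm(n, 580, 25))
  des <- make_design(subjects)
  maps <- array(rnorm(prod(grid$dims) * n), c(grid$dims, n))
  st <- glm_contrast_tmap(maps, des, mask = mask, grid = grid)
  expect_equal(st$dof, n - 6)
  y <- maps[2, 3, 1, ]
  fit <- lm(y ~ des$X - 1)
  tval <- summary(fit)$coefficients["des$Xgroup", "t value"]
  expect_equal(st$t_values[2, 3, 1], unname(tval), tolerance = 1e-10)
  expect_error(glm_contrast_tmap(maps, cbind(des$X, des$X[, 2]),
                                 contrast = rep(0, 7), mask = mask,
                                 grid = grid), "rank")
})

test_that("one-sample degenerate variance is flagged", {
  grid <- volume_grid(c(3, 3, 3), 3)
  mask <- array(TRUE, c(3, 3, 3))
  maps <- array(2, c(3, 3, 3, 5))          # constant nonzero, zero variance
  X <- matrix(1, 5, 1)
  expect_warning(st <- glm_contrast_tmap(maps, X, contrast = 1, mask = mask,
                                         grid = grid), "degenerate")
  expect_true(all(is.infinite(st$t_values[mask]) & st$t_values[mask] > 0))
})

test_that("estimate_fwhm recovers applied smoothing and is monotone", {
  grid <- volume_grid(c(16, 16, 12), 3)
  mask <- array(TRUE, c(16, 16, 12))
  set.seed(41)
  res <- array(rnorm(prod(grid$dims) * 8), c(grid$dims, 8))
  est <- numeric(3)
  fwhms <- c(0, 4, 8)
  for (i in seq_along(fwhms)) {
    sm <- if (fwhms[i] == 0) res else
      rehoconn:::smooth_stack(res, rep(fwhms[i] / 2.3548 / 3, 3))
    est[i] <- mean(estimate_fwhm(sm, grid, mask)$fwhm_mm)
  }
  expect_lt(est[1], 1.2 * 3)                  # unsmoothed: under 1.2 voxels
  expect_equal(est[3], 8, tolerance = 0.15)   # 8 mm within 15%
  expect_true(all(diff(est) > 0))             # monotone in applied smoothing
  expect_error(estimate_fwhm(array(1, c(16, 16, 12, 3)), grid, mask),
               "constant")
})

test_that("label_clusters agrees with an independent flood-fill oracle", {
  # oracle: repeated neighbour dilation from each unvisited voxel
  oracle_label <- function(flags, connectivity) {
    d <- dim(flags)
    offs <- connectivity_offsets(connectivity)
    comp <- array(0L, d)
    nxt <- 0L
    coords <- which(flags, arr.ind = TRUE)
    key <- function(v) paste(v, collapse = ",")
    lookup <- new.env()
    for (i in seq_len(nrow(coords)))
      assign(key(coords[i, ]), i, envir = lookup)
    for (i in seq_len(nrow(coords))) {
      if (comp[coords[i, , drop = FALSE]] != 0L) next
      nxt <- nxt + 1L
      frontier <- list(coords[i, ])
      comp[matrix(coords[i, ], 1)] <- nxt
      while (length(frontier)) {
        nf <- list()
        for (v in frontier) for (o in seq_len(nrow(offs))) {
          w <- v + offs[o, ]
          if (any(w < 1) || any(w > d)) next
          if (!flags[matrix(w, 1)]) next
          if (comp[matrix(w, 1)] == 0L) {
            comp[matrix(w, 1)] <- nxt
            nf[[length(nf) + 1L]] <- w
          }
        }
        frontier <- nf
      }
    }
    comp
  }
  set.seed(55)
  for (conn in c(6L, 18L, 26L)) {
    flags <- array(runif(10 * 10 * 6) < 0.2, c(10, 10, 6))
    got <- label_clusters(flags, conn)
    want <- oracle_label(flags, conn)
    # same partition up to label permutation
    expect_equal(length(got$sizes), max(want))
    expect_true(all(got$labels[!flags] == 0L))
    for (k in seq_len(max(want))) {
      members <- which(want == k)
      expect_equal(length(unique(got$labels[members])), 1L)
      expect_equal(got$sizes[got$labels[members[1]]], length(members))
    }
  }
})

test_that("extract_clusters applies min_extent and sign separation", {
  grid <- volume_grid(c(10, 10, 6), 3)
  mask <- array(TRUE, c(10, 10, 6))
  tv <- array(0, c(10, 10, 6))
  tv[2:2, 2:6, 2] <- 10       # 5-voxel positive blob
  tv[8, 8:8, 2:4] <- 10       # 3-voxel positive blob
  tv[5, 5, 5] <- -10          # below min_extent, negative
  st <- structure(list(t_values = tv, dof = 20, mask = mask, grid = grid),
                  class = "stat_map")
  cl <- extract_clusters(st, p_voxel = 0.01, min_extent = 4)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_voxels, 5)
  expect_equal(cl$sign, "positive")
  zero <- st
  zero$t_values[] <- 0
  expect_equal(nrow(extract_clusters(zero, 0.01, 1)), 0)
})

test_that("alphasim trivial bounds hold and results are seed-deterministic", {
  g3 <- volume_grid(c(3, 3, 3), 3)
  m1 <- array(FALSE, c(3, 3, 3)); m1[2, 2, 2] <- TRUE
  expect_equal(as.integer(alphasim_min_extent(m1, g3, 0, 0.01, 0.05,
                                              n_iterations = 300,
                                              rng_seed = 2)), 1L)
  g <- volume_grid(c(12, 12, 8), 3)
  mask <- array(TRUE, c(12, 12, 8))
  expect_equal(as.integer(alphasim_min_extent(mask, g, 0, 0.01, alpha = 1,
                                              n_iterations = 10,
                                              rng_seed = 1)), 1L)
  a <- alphasim_min_extent(mask, g, 6, 0.01, 0.05, n_iterations = 200,
                           rng_seed = 7)
  b <- alphasim_min_extent(mask, g, 6, 0.01, 0.05, n_iterations = 200,
                           rng_seed = 7)
  expect_identical(as.integer(a), as.integer(b))
  expect_identical(attr(a, "max_sizes"), attr(b, "max_sizes"))
})

test_that("alphasim matches an independently coded simulator and is monotone", {
  # independent oracle: plain-R simulation with its own smoothing (FFT-based
  # circular convolution) and cluster counting via label_clusters
  oracle_alphasim <- function(dims, fwhm_vox, p_voxel, alpha, iters, seed) {
    set.seed(seed)
    sig <- fwhm_vox / (2 * sqrt(2 * log(2)))
    zc <- qnorm(1 - p_voxel / 2)
    maxes <- integer(iters)
    for (it in seq_len(iters)) {
      f <- array(rnorm(prod(dims)), dims)
      if (sig > 0) {
        k1 <- dnorm(seq(-dims[1] / 2, dims[1] / 2 - 1), sd = sig)
        k2 <- dnorm(seq(-dims[2] / 2, dims[2] / 2 - 1), sd = sig)
        k3 <- dnorm(seq(-dims[3] / 2, dims[3] / 2 - 1), sd = sig)
        K <- outer(outer(k1, k2), k3)
        K <- K / sum(K)
        f <- Re(fft(fft(f) * Conj(fft(K)), inverse = TRUE)) / prod(dims)
      }
      z <- (f - mean(f)) / sd(f)
      sz <- label_clusters(abs(z) > zc, 26L)$sizes
      maxes[it] <- if (length(sz)) max(sz) else 0L
    }
    s <- 1L
    while (mean(maxes >= s) > alpha) s <- s + 1L
    s
  }
  g <- volume_grid(c(16, 16, 12), 3)
  mask <- array(TRUE, c(16, 16, 12))
  mine <- as.integer(alphasim_min_extent(mask, g, fwhm_mm = 6, p_voxel = 0.01,
                                         alpha = 0.05, n_iterations = 400,
                                         rng_seed = 3))
  theirs <- oracle_alphasim(c(16, 16, 12), 2, 0.01, 0.05, 400, 1234)
  expect_lte(abs(mine - theirs), 2)
  # monotonicity: non-increasing in alpha, non-decreasing in p and smoothness
  m_a <- sapply(c(0.02, 0.05, 0.10), function(a)
    as.integer(alphasim_min_extent(mask, g, 6, 0.01, a, n_iterations = 200,
                                   rng_seed = 9)))
  expect_true(all(diff(m_a) <= 0))
  m_f <- sapply(c(0, 6), function(f)
    as.integer(alphasim_min_extent(mask, g, f, 0.01, 0.05,
                                   n_iterations = 200, rng_seed = 9)))
  expect_true(all(diff(m_f) >= 0))
})

test_that("seeds_from_clusters keeps positive clusters disjoint", {
  grid <- volume_grid(c(10, 10, 6), 3)
  mask <- array(TRUE, c(10, 10, 6))
  tv <- array(0, c(10, 10, 6))
  tv[2:3, 2:3, 2:3] <- 8
  tv[7:8, 7:8, 2:3] <- 8
  tv[5, 5, 5] <- -8
  st <- structure(list(t_values = tv, dof = 30, mask = mask, grid = grid),
                  class = "stat_map")
  cl <- extract_clusters(st, 0.01, 1)
  expect_equal(sum(cl$sign == "positive"), 2)
  expect_equal(sum(cl$sign == "negative"), 1)
  seeds <- seeds_from_clusters(cl)
  expect_length(seeds, 2)
  all_vox <- do.call(rbind, lapply(seeds, `[[`, "voxels"))
  expect_equal(nrow(all_vox), nrow(unique(all_vox)))   # disjoint
  expect_warning(empty <- seeds_from_clusters(cl[cl$sign == "negative", ],
                                              sign = "positive"), "no positive")
  expect_length(empty, 0)
})

test_that("build_connectivity_mask unions the two groups' significant sets", {
  grid <- volume_grid(c(10, 10, 6), 3)
  mask <- array(TRUE, c(10, 10, 6))
  mk_stat <- function(where) {
    tv <- array(0, c(10, 10, 6))
    tv[where] <- 9
    structure(list(t_values = tv, dof = 25, mask = mask, grid = grid),
              class = "stat_map")
  }
  a_vox <- array(FALSE, c(10, 10, 6)); a_vox[2:3, 2:3, 2:3] <- TRUE
  b_vox <- array(FALSE, c(10, 10, 6)); b_vox[7:8, 7:8, 4:5] <- TRUE
  st_a <- mk_stat(a_vox); st_b <- mk_stat(b_vox)
  un <- build_connectivity_mask(st_a, st_b, 0.01, 1)
  expect_equal(un, a_vox | b_vox)
  same <- build_connectivity_mask(st_a, st_a, 0.01, 1)
  expect_equal(same, a_vox)
  none <- mk_stat(array(FALSE, c(10, 10, 6)))
  expect_warning(empty <- build_connectivity_mask(none, none, 0.01, 1),
                 "no significant")
  expect_false(any(empty))
})
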