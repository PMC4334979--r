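test_that("identical spec and seed reproduce the cohort bit-for-bit", {
  cs <- small_cohort_spec(n_a = 2, n_b = 2, n_volumes = 40, seed = 99)
  a <- generate_cohort(cs)
  b <- generate_cohort(cs)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$series[[1]]$data, b$series[[1]]$data)
  expect_identical(a$motion, b$motion)
  expect_identical(a$truth$betas, b$truth$betas)
})

test_that("null couplings give near-zero within-sphere correlation", {
  cs <- small_cohort_spec(n_a = 1, n_b = 1, n_volumes = 240, seed = 5,
                          local_a = 0, local_b = 0, slope = 0, slope_b = 0,
                          drift_amplitude = 0, nuisance_amplitude = 0,
                          beta_sd = 0, plant_motion_outlier = FALSE)
  co <- generate_cohort(cs)
  loc <- lin_index(co$truth$effects[[1]]$local_voxels, co$grid$dims)
  nt <- 240
  mat <- t(matrix(co$series[[1]]$data, prod(co$grid$dims), nt))[, loc]
  cm <- cor(mat)
  off <- cm[upper.tri(cm)]
  expect_lt(abs(mean(off)), 3 / sqrt(nt))
})

test_that("planted local coupling produces the requested pairwise correlation", {
  # simulation oracle: mean pairwise correlation over ~100 voxel pairs
  cs <- small_cohort_spec(n_a = 1, n_b = 1, n_volumes = 240, seed = 17,
                          local_a = 0.5, local_b = 0.25, slope = 0,
                          slope_b = 0, beta_sd = 0,
                          drift_amplitude = 0, nuisance_amplitude = 0,
                          plant_motion_outlier = FALSE)
  co <- generate_cohort(cs)
  loc <- lin_index(co$truth$effects[[1]]$local_voxels, co$grid$dims)
  pick <- loc[seq(1, length(loc), length.out = 15)]
  get_mean_r <- function(id) {
    mat <- t(matrix(co$series[[id]]$data, prod(co$grid$dims), 240))[, pick]
    cm <- cor(mat)
    mean(cm[upper.tri(cm)])              # ~100 pairs
  }
  r_patient <- get_mean_r(which(co$subjects$group == "patient")[1])
  r_control <- get_mean_r(which(co$subjects$group == "control")[1])
  expect_equal(r_patient, 0.5, tolerance = 0.12)
  expect_equal(r_control, 0.25, tolerance = 0.2)
})

test_that("simulated THQ tracks the coupling deviate at the analytic strength", {
  cs <- small_cohort_spec(n_a = 200, n_b = 2, n_volumes = 40, seed = 23)
  cs$n_volumes <- 40
  # subjects only: skip series generation cost by tiny volume count
  co <- generate_cohort(cs)
  pat <- co$subjects$group == "patient"
  r <- cor(co$subjects$thq[pat], co$truth$coupling_z[pat, 1])
  rho <- 34 / sqrt(34^2 + 66^2)          # score_link / sqrt(link^2 + noise^2)
  ci <- tanh(atanh(rho) + c(-3, 3) / sqrt(sum(pat) - 3))
  expect_gt(r, ci[1])
  expect_lt(r, ci[2])
  expect_gt(cor(co$subjects$thq[pat], co$subjects$true_coupling[pat]), 0)
})

test_that("spec invariants are enforced", {
  expect_error(cohort_spec(n_volumes = 10), "exceed 10")
  expect_error(cohort_spec(grid_dims = c(6, 24, 16)), ">= 8")
  expect_error(cohort_spec(noise_sd = 0), "positive")
  expect_error(planted_effect(local_coupling_a = 1), "\\[0, 1\\)")
  bad <- small_cohort_spec(n_a = 1, n_b = 1, n_volumes = 20)
  bad$planted_effects[[1]]$center_mm <- c(18, 0, 0)   # pokes outside the mask
  expect_error(generate_cohort(bad), "outside the brain mask")
})

test_that("mask is a nonempty ellipsoid strictly inside the grid", {
  co <- generate_cohort(small_cohort_spec(n_a = 1, n_b = 1, n_volumes = 20,
                                          plant_motion_outlier = FALSE))
  m <- co$mask
  expect_true(any(m))
  expect_true(all(!m[1, , ]) && all(!m[dim(m)[1], , ]))
  expect_true(all(!m[, , 1]) && all(!m[, , dim(m)[3]]))
  # every voxel series has finite variance
  v <- apply(t(matrix(co$series[[1]]$data, prod(co$grid$dims), 20))[, m], 2, var)
  expect_true(all(is.finite(v) & v > 0))
})

test_that("the planted motion outlier is the only subject breaching the limits", {
  co <- generate_cohort(small_cohort_spec(n_a = 3, n_b = 3, n_volumes = 30,
                                          seed = 31))
  inc <- vapply(co$motion, function(m) motion_screen(m)$included, logical(1))
  expect_equal(sum(!inc), 1L)
  expect_equal(names(inc)[!inc], co$truth$motion_outlier)
})

test_that("write_fixtures round trips arrays and lists one motion file per subject", {
  co <- generate_cohort(small_cohort_spec(n_a = 2, n_b = 1, n_volumes = 15,
                                          seed = 13,
                                          plant_motion_outlier = FALSE))
  dir <- withr::local_tempdir()
  man <- write_fixtures(co, dir)
  expect_length(man$motion, nrow(co$subjects))
  id <- co$subjects$subject_id[1]
  s2 <- load_series(man$series[[id]], man$mask)
  expect_equal(s2$data, co$series[[id]]$data)
  expect_equal(s2$mask, co$mask)
  m2 <- read_motion_params(man$motion[[id]])
  expect_equal(as.matrix(m2), as.matrix(co$motion[[id]]), tolerance = 1e-15)
  tab <- read.delim(man$subjects)
  expect_equal(tab$subject_id, co$subjects$subject_id)
  # truth manifest sphere voxel counts match brute-force rasterisation
  truth <- jsonlite::read_json(man$truth, simplifyVector = TRUE)
  e <- co$spec$planted_effects[[1]]
  ijk <- arrayInd(seq_len(prod(co$grid$dims)), co$grid$dims)
  mm <- voxel_to_mm(co$grid, ijk)
  n_local <- sum(sqrt(rowSums(sweep(mm, 2, e$center_mm)^2)) <= e$radius_mm)
  expect_equal(truth$effects$n_local_voxels, n_local)
})
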