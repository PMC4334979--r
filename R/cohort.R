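#' Planted synchrony/connectivity effect
#'
#' Describes one ground-truth effect in a simulated cohort: a local sphere
#' whose voxels share a latent signal (fraction of variance
#' `local_coupling_a` in group A = patients, `local_coupling_b` in group B =
#' controls), and optionally a remote sphere coupled to the local sphere
#' through a second shared latent whose per-subject weight beta drives a
#' simulated severity score.
#'
#' Per subject, `beta = slope_group + beta_sd * z` where `z ~ N(0,1)` is the
#' subject's standardised coupling deviate (`slope_group` is
#' `connectivity_slope` for patients, `connectivity_slope_b` for controls),
#' and the simulated THQ is `intercept + score_link * z + noise` so that the
#' THQ-coupling correlation has the closed form
#' `score_link / sqrt(score_link^2 + thq_noise_sd^2)`.
#'
#' @param center_mm local sphere centre (mm, length 3).
#' @param radius_mm local sphere radius (mm).
#' @param local_coupling_a,local_coupling_b shared-variance fraction per
#'   group, each in `[0, 1)`.
#' @param remote_center_mm remote sphere centre (mm) or NULL for none.
#' @param remote_radius_mm remote sphere radius (mm).
#' @param connectivity_slope mean seed-remote coupling beta for patients.
#' @param connectivity_slope_b mean beta for controls (default 40% of the
#'   patient slope, giving the group difference the two-sample contrast
#'   should detect).
#' @param score_link weight of the subject coupling deviate in the simulated
#'   THQ score.
#' @return List of class `planted_effect`.
#' @export
planted_effect <- function(center_mm = c(-13.5, 10.5, 4.5), radius_mm = 9,
                           local_coupling_a = 0.5, local_coupling_b = 0.25,
                           remote_center_mm = c(13.5, -10.5, 4.5),
                           remote_radius_mm = 9,
                           connectivity_slope = 0.8,
                           connectivity_slope_b = 0.4 * connectivity_slope,
                           score_link = 34) {
  if (local_coupling_a < 0 || local_coupling_a >= 1 ||
      local_coupling_b < 0 || local_coupling_b >= 1)
    stop("local couplings must lie in [0, 1)")
  if (radius_mm <= 0) stop("radius must be positive")
  structure(list(center_mm = center_mm, radius_mm = radius_mm,
                 local_coupling_a = local_coupling_a,
                 local_coupling_b = local_coupling_b,
                 remote_center_mm = remote_center_mm,
                 remote_radius_mm = remote_radius_mm,
                 connectivity_slope = connectivity_slope,
                 connectivity_slope_b = connectivity_slope_b,
                 score_link = score_link),
            class = "planted_effect")
}

#' Default covariate distributions for the simulated cohort
#'
#' Normal (mean, sd) summaries per group for age, education, gray- and
#' white-matter volume, anxiety/depression scores and (patients only)
#' symptom duration, plus a Bernoulli male probability; values emulate a
#' typical chronic-tinnitus case-control sample (~29 patients, ~30 matched
#' controls).
#'
#' @return Nested list `list(patient = ..., control = ...)`.
#' @export
default_covariate_distributions <- function() {
  list(
    patient = list(age_years = c(40.9, 10.5), education_years = c(10.9, 2.2),
                   gm_volume_ml = c(581.2, 26.4), wm_volume_ml = c(531.6, 25.6),
                   sas = c(38, 6), sds = c(38, 6),
                   duration_months = c(39.5, 33.7), p_male = 16 / 29),
    control = list(age_years = c(46.2, 11.9), education_years = c(11.1, 1.7),
                   gm_volume_ml = c(576.1, 22.1), wm_volume_ml = c(528.8, 25.4),
                   sas = c(38, 6), sds = c(38, 6),
                   duration_months = NULL, p_male = 15 / 30))
}

#' Specification of a synthetic two-group resting-state cohort
#'
#' Defaults emulate a desk-scale version of a chronic-tinnitus resting-state
#' study: 29 patients and 30 controls, 240 acquired volumes at TR 2 s (of
#' which the first 10 are dummies, leaving 230 analysed), 3 mm voxels on a
#' 24 x 24 x 16 grid with an ellipsoidal brain mask, one planted
#' local-synchrony + seed-to-remote effect, linear drift, bounded
#' random-walk motion, and global/WM/CSF-like nuisance signals.  When
#' `plant_motion_outlier` is TRUE one extra patient is generated whose
#' motion exceeds the 2 mm screening limit, exercising subject exclusion.
#'
#' @param n_group_a,n_group_b analysed subjects per group (patients,
#'   controls).
#' @param grid_dims 3 integers, all >= 8.
#' @param voxel_size_mm isotropic voxel size (mm).
#' @param tr_s repetition time (s).
#' @param n_volumes acquired volumes (> 10).
#' @param mask_radius_mm in-plane semi-axis of the ellipsoidal mask; the
#'   through-plane semi-axis is capped just inside the grid.
#' @param planted_effects list of [planted_effect()] (may be empty).
#' @param noise_sd voxel noise standard deviation (> 0).
#' @param drift_amplitude per-voxel linear drift amplitude, in noise-sd
#'   units over the run.
#' @param motion_sd_mm,motion_sd_deg random-walk step sd for translations /
#'   rotations.
#' @param nuisance_amplitude amplitude of the shared global/WM/CSF-like
#'   signals, in noise-sd units.
#' @param beta_sd between-subject sd of the seed-remote coupling beta.
#' @param thq_intercept,thq_noise_sd intercept and residual sd of the
#'   simulated THQ score.
#' @param covariate_distributions see [default_covariate_distributions()].
#' @param plant_motion_outlier generate one extra high-motion patient.
#' @param rng_seed integer seed; the cohort is fully reproducible from it.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_group_a = 29, n_group_b = 30,
                        grid_dims = c(24, 24, 16), voxel_size_mm = 3,
                        tr_s = 2, n_volumes = 240, mask_radius_mm = 33,
                        planted_effects = list(planted_effect()),
                        noise_sd = 1, drift_amplitude = 0.5,
                        motion_sd_mm = 0.05, motion_sd_deg = 0.05,
                        nuisance_amplitude = 0.3, beta_sd = 0.2,
                        thq_intercept = 103.5, thq_noise_sd = 66,
                        covariate_distributions = default_covariate_distributions(),
                        plant_motion_outlier = TRUE, rng_seed = 1L) {
  if (n_volumes <= 10) stop("n_volumes must exceed 10 (the dummy count)")
  if (any(grid_dims < 8)) stop("all grid dims must be >= 8")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (n_group_a < 1 || n_group_b < 1) stop("need subjects in both groups")
  structure(list(n_group_a = as.integer(n_group_a),
                 n_group_b = as.integer(n_group_b),
                 grid_dims = as.integer(grid_dims),
                 voxel_size_mm = voxel_size_mm, tr_s = tr_s,
                 n_volumes = as.integer(n_volumes),
                 mask_radius_mm = mask_radius_mm,
                 planted_effects = planted_effects, noise_sd = noise_sd,
                 drift_amplitude = drift_amplitude,
                 motion_sd_mm = motion_sd_mm, motion_sd_deg = motion_sd_deg,
                 nuisance_amplitude = nuisance_amplitude, beta_sd = beta_sd,
                 thq_intercept = thq_intercept, thq_noise_sd = thq_noise_sd,
                 covariate_distributions = covariate_distributions,
                 plant_motion_outlier = isTRUE(plant_motion_outlier),
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

# ellipsoidal brain mask centred in the grid
ellipsoid_mask <- function(grid, radius_mm) {
  half <- grid$dims * grid$voxel_size_mm / 2
  semi <- pmin(radius_mm, half - grid$voxel_size_mm)
  ijk <- arrayInd(seq_len(prod(grid$dims)), grid$dims)
  mm <- voxel_to_mm(grid, ijk)
  inside <- rowSums(sweep(mm, 2L, semi, "/")^2) <= 1
  array(inside, dim = grid$dims)
}

# linear indices of in-mask voxels within a sphere; errors if the sphere
# pokes outside the mask or rasterises to nothing
sphere_voxels <- function(grid, mask, center_mm, radius_mm, what = "sphere") {
  ijk <- arrayInd(seq_len(prod(grid$dims)), grid$dims)
  mm <- voxel_to_mm(grid, ijk)
  inside <- rowSums(sweep(mm, 2L, center_mm)^2) <= radius_mm^2
  if (!any(inside)) stop(what, " rasterises to zero voxels")
  if (any(inside & !as.vector(mask)))
    stop(what, " extends outside the brain mask")
  which(inside)
}

# band-limited unit-variance latent signals: white noise restricted to the
# analysis band so planted structure survives the preprocessing filter
band_limited_latent <- function(nt, tr_s, k = 1L, low_hz = 0.01,
                                high_hz = 0.08) {
  f <- (seq_len(nt) - 1) / (nt * tr_s)
  keep <- pmin(f, 1 / tr_s - f) >= low_hz & pmin(f, 1 / tr_s - f) <= high_hz
  x <- matrix(stats::rnorm(nt * k), nt, k)
  ft <- stats::mvfft(x)
  ft[!keep, ] <- 0
  y <- Re(stats::mvfft(ft, inverse = TRUE)) / nt
  sweep(y, 2L, apply(y, 2L, stats::sd), "/")
}

# triangle-wave fold of x into [-b, b]
fold_into <- function(x, b) {
  y <- (x + b) %% (4 * b)
  b - abs(y - 2 * b)
}

# bounded random-walk motion table; optionally scaled to breach the limit
simulate_motion <- function(nt, sd_mm, sd_deg, outlier = FALSE) {
  walk <- function(sd, b) fold_into(cumsum(stats::rnorm(nt, 0, sd)), b)
  m <- cbind(walk(sd_mm, 1.5), walk(sd_mm, 1.5), walk(sd_mm, 1.5),
             walk(sd_deg, 1.5), walk(sd_deg, 1.5), walk(sd_deg, 1.5))
  if (outlier) {
    mx <- max(abs(m[, 1]))
    m[, 1] <- m[, 1] * (2.5 / max(mx, .Machine$double.eps))
  }
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  tibble::as_tibble(m)
}

draw_norm <- function(n, ms) stats::rnorm(n, ms[1], ms[2])

#' Generate a synthetic two-group resting-state cohort
#'
#' Draws subjects (demographics, clinical scores), 4D BOLD series with the
#' planted effects of the spec, motion parameter tables and nuisance
#' signals.  Inside each planted local sphere a voxel's series is
#' `sqrt(1 - c) * noise + sqrt(c) * latent` (coupling `c` per group); the
#' local and remote spheres additionally receive `beta * shared_latent`
#' with per-subject `beta`; every in-mask voxel receives linear drift and
#' the global/WM/CSF-like nuisance signals.  The simulated THQ score is
#' linearly linked to the subject's coupling deviate.  Fully reproducible
#' from `spec$rng_seed`.
#'
#' @param spec a [cohort_spec()].
#' @return List of class `cohort`: `subjects` (tibble; includes
#'   `true_coupling`), `series` (named list of [bold_series()]), `motion`
#'   (named list of tibbles), `mask`, `grid`, and `truth` (planted voxel
#'   indices, per-subject betas and coupling deviates, nuisance signals,
#'   spec echo).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  grid <- volume_grid(spec$grid_dims, spec$voxel_size_mm)
  mask <- ellipsoid_mask(grid, spec$mask_radius_mm)
  if (!any(mask)) stop("mask is empty")
  nt <- spec$n_volumes
  effects <- spec$planted_effects
  eff_vox <- lapply(seq_along(effects), function(i) {
    e <- effects[[i]]
    loc <- sphere_voxels(grid, mask, e$center_mm, e$radius_mm,
                         sprintf("effect %d local sphere", i))
    rem <- if (!is.null(e$remote_center_mm))
      sphere_voxels(grid, mask, e$remote_center_mm, e$remote_radius_mm,
                    sprintf("effect %d remote sphere", i)) else integer(0)
    list(local = loc, remote = rem)
  })

  with_local_seed(spec$rng_seed, {
    n_out <- if (spec$plant_motion_outlier) 1L else 0L
    na <- spec$n_group_a + n_out
    nb <- spec$n_group_b
    n <- na + nb
    ids <- sprintf("S%03d", seq_len(n))
    group <- c(rep("patient", na), rep("control", nb))
    cd <- spec$covariate_distributions

    draw_group <- function(field, g, ng)
      draw_norm(ng, cd[[g]][[field]])
    subjects <- tibble::tibble(
      subject_id = ids, group = group,
      age_years = c(draw_group("age_years", "patient", na),
                    draw_group("age_years", "control", nb)),
      sex = ifelse(stats::runif(n) < c(rep(cd$patient$p_male, na),
                                       rep(cd$control$p_male, nb)),
                   "male", "female"),
      education_years = c(draw_group("education_years", "patient", na),
                          draw_group("education_years", "control", nb)),
      gm_volume_ml = c(draw_group("gm_volume_ml", "patient", na),
                       draw_group("gm_volume_ml", "control", nb)),
      wm_volume_ml = c(draw_group("wm_volume_ml", "patient", na),
                       draw_group("wm_volume_ml", "control", nb)))

    # per-effect, per-subject coupling deviates and betas
    ne <- length(effects)
    zmat <- matrix(stats::rnorm(n * ne), n, ne)
    betas <- matrix(0, n, ne)
    for (i in seq_len(ne)) {
      e <- effects[[i]]
      slope <- ifelse(group == "patient", e$connectivity_slope,
                      e$connectivity_slope_b)
      betas[, i] <- slope + spec$beta_sd * zmat[, i]
    }

    is_pat <- group == "patient"
    link <- if (length(effects))
      as.vector(zmat %*% vapply(effects, `[[`, numeric(1), "score_link"))
    else rep(0, n)
    thq <- ifelse(is_pat, spec$thq_intercept + link +
                    stats::rnorm(n, 0, spec$thq_noise_sd), NA_real_)
    subjects$thq <- thq
    subjects$sas <- draw_norm(n, cd$patient$sas)
    subjects$sds <- draw_norm(n, cd$patient$sds)
    dur <- if (!is.null(cd$patient$duration_months))
      pmax(1, draw_norm(n, cd$patient$duration_months)) else rep(NA_real_, n)
    subjects$duration_months <- ifelse(is_pat, dur, NA_real_)
    subjects$true_coupling <- if (length(effects)) betas[, 1] else NA_real_

    outlier_flag <- c(rep(FALSE, n))
    if (n_out) outlier_flag[na] <- TRUE   # the extra patient breaches limits

    vox_in <- which(mask)
    V <- length(vox_in)
    loc_id <- lapply(eff_vox, function(ev) match(ev$local, vox_in))
    rem_id <- lapply(eff_vox, function(ev) match(ev$remote, vox_in))
    tnorm <- 2 * (seq_len(nt) - (nt + 1) / 2) / nt
    nuis_w <- c(global = 1, wm = 0.6, csf = 0.6)

    series <- vector("list", n)
    motion <- vector("list", n)
    nuisance <- vector("list", n)
    names(series) <- names(motion) <- names(nuisance) <- ids
    for (s in seq_len(n)) {
      sig <- matrix(stats::rnorm(nt * V), nt, V)
      for (i in seq_along(effects)) {
        e <- effects[[i]]
        cc <- if (is_pat[s]) e$local_coupling_a else e$local_coupling_b
        u <- band_limited_latent(nt, spec$tr_s)
        li <- loc_id[[i]]
        sig[, li] <- sqrt(1 - cc) * sig[, li] +
          sqrt(cc) * matrix(u, nt, length(li))
        if (length(rem_id[[i]])) {
          w <- band_limited_latent(nt, spec$tr_s)
          b <- betas[s, i]
          both <- c(li, rem_id[[i]])
          sig[, both] <- sig[, both] + b * matrix(w, nt, length(both))
        }
      }
      if (spec$drift_amplitude != 0)
        sig <- sig + outer(tnorm, spec$drift_amplitude * stats::rnorm(V))
      nu <- band_limited_latent(nt, spec$tr_s, k = 3L)
      colnames(nu) <- names(nuis_w)
      if (spec$nuisance_amplitude != 0)
        sig <- sig + spec$nuisance_amplitude *
          matrix(nu %*% nuis_w, nt, V)
      dat <- array(0, dim = c(grid$dims, nt))
      dm <- matrix(dat, ncol = nt)
      dm[vox_in, ] <- t(spec$noise_sd * sig)
      series[[s]] <- bold_series(array(dm, dim = c(grid$dims, nt)), grid,
                                 spec$tr_s, mask)
      motion[[s]] <- simulate_motion(nt, spec$motion_sd_mm, spec$motion_sd_deg,
                                     outlier = outlier_flag[s])
      nuisance[[s]] <- nu
    }

    truth <- list(effects = lapply(seq_along(effects), function(i) list(
                    local_voxels = arrayInd(eff_vox[[i]]$local, grid$dims),
                    remote_voxels = if (length(eff_vox[[i]]$remote))
                      arrayInd(eff_vox[[i]]$remote, grid$dims)
                    else matrix(integer(0), 0, 3),
                    params = effects[[i]])),
                  betas = betas, coupling_z = zmat,
                  nuisance = nuisance, motion_outlier = ids[outlier_flag],
                  rng_seed = spec$rng_seed)
    structure(list(subjects = subjects, series = series, motion = motion,
                   mask = mask, grid = grid, truth = truth, spec = spec),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d patients + %d controls, %s grid, %d volumes\n",
              sum(x$subjects$group == "patient"),
              sum(x$subjects$group == "control"),
              paste(x$grid$dims, collapse = "x"),
              n_volumes(x$series[[1]])))
  invisible(x)
}

#' Write a cohort to disk as standard-format fixtures
#'
#' Writes per-subject NIfTI-1 series and motion text files, the mask, a TSV
#' subject table, a JSON ground-truth manifest and per-subject nuisance
#' signal files; all arrays round-trip exactly.
#'
#' @param cohort from [generate_cohort()].
#' @param out_dir output directory (created if needed).
#' @return The manifest (named list of written files), invisibly written as
#'   `manifest.json` too.
#' @export
write_fixtures <- function(cohort, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create ", out_dir)
  mask_path <- file.path(out_dir, "mask.nii.gz")
  write_nifti_grid(array(as.numeric(cohort$mask), dim = cohort$grid$dims),
                   cohort$grid, mask_path)
  ids <- cohort$subjects$subject_id
  series_files <- motion_files <- nuisance_files <- character(length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    series_files[i] <- file.path(out_dir, paste0("bold_", id, ".nii.gz"))
    save_map(cohort$series[[id]]$data, cohort$grid, series_files[i],
             tr_s = cohort$series[[id]]$tr_s)
    motion_files[i] <- file.path(out_dir, paste0("motion_", id, ".txt"))
    write_motion_params(cohort$motion[[id]], motion_files[i])
    nuisance_files[i] <- file.path(out_dir, paste0("nuisance_", id, ".txt"))
    utils::write.table(format(as.data.frame(cohort$truth$nuisance[[id]]),
                              digits = 17, scientific = TRUE, trim = TRUE),
                       nuisance_files[i], row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  subj_path <- file.path(out_dir, "subjects.tsv")
  utils::write.table(as.data.frame(cohort$subjects), subj_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  truth_path <- file.path(out_dir, "truth.json")
  truth <- list(
    rng_seed = cohort$truth$rng_seed,
    motion_outlier = cohort$truth$motion_outlier,
    betas = cohort$truth$betas,
    coupling_z = cohort$truth$coupling_z,
    effects = lapply(cohort$truth$effects, function(e) list(
      n_local_voxels = nrow(e$local_voxels),
      n_remote_voxels = nrow(e$remote_voxels),
      local_voxels = e$local_voxels,
      remote_voxels = e$remote_voxels,
      center_mm = e$params$center_mm,
      radius_mm = e$params$radius_mm,
      remote_center_mm = e$params$remote_center_mm,
      remote_radius_mm = e$params$remote_radius_mm,
      local_coupling_a = e$params$local_coupling_a,
      local_coupling_b = e$params$local_coupling_b,
      connectivity_slope = e$params$connectivity_slope,
      connectivity_slope_b = e$params$connectivity_slope_b,
      score_link = e$params$score_link)))
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  manifest <- list(mask = mask_path, subjects = subj_path, truth = truth_path,
                   series = as.list(stats::setNames(series_files, ids)),
                   motion = as.list(stats::setNames(motion_files, ids)),
                   nuisance = as.list(stats::setNames(nuisance_files, ids)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}
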