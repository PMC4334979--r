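#' Full-pipeline configuration
#'
#' Bundles every stage setting with the conventional defaults: band-pass
#' 0.01-0.08 Hz, 10 discarded volumes, 4 mm FWHM, 27-voxel neighbourhood,
#' voxelwise p = 0.01 with Monte-Carlo cluster correction, covariates age /
#' sex / education / GM volume, scores THQ / SAS / SDS / duration.  Can
#' also be read from a YAML file whose keys mirror the arguments.
#'
#' @param cohort_spec a [cohort_spec()] describing the simulated input (the
#'   pipeline currently runs on simulated cohorts; fixtures written with
#'   [write_fixtures()] can be loaded back with [load_series()] and fed to
#'   the stage functions directly).
#' @param preprocess a [preprocess_config()].
#' @param neighbourhood ReHo neighbourhood (7/19/27).
#' @param p_voxel,alpha,connectivity,n_iterations cluster criterion; see
#'   [alphasim_min_extent()].
#' @param covariates,scores column names used for the design and the
#'   brain-behaviour correlations.
#' @param rng_seed top-level seed, fanned out deterministically to the
#'   simulation and Monte-Carlo stages.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_spec = rehoconn::cohort_spec(),
                            preprocess = preprocess_config(),
                            neighbourhood = 27L, p_voxel = 0.01,
                            alpha = 0.05, connectivity = 26L,
                            n_iterations = 1000L,
                            covariates = c("age_years", "sex",
                                           "education_years", "gm_volume_ml"),
                            scores = c("thq", "sas", "sds", "duration_months"),
                            rng_seed = 1L) {
  stopifnot(p_voxel > 0, p_voxel < 1, alpha > 0, alpha < 1)
  structure(list(cohort_spec = cohort_spec, preprocess = preprocess,
                 neighbourhood = as.integer(neighbourhood),
                 p_voxel = p_voxel, alpha = alpha,
                 connectivity = as.integer(connectivity),
                 n_iterations = as.integer(n_iterations),
                 covariates = covariates, scores = scores,
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror [pipeline_config()] arguments; `cohort_spec` and
#' `preprocess` are nested maps passed to their constructors.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$cohort_spec)) {
    cs <- y$cohort_spec
    if (!is.null(cs$planted_effects))
      cs$planted_effects <- lapply(cs$planted_effects,
                                   function(pe) do.call(planted_effect, pe))
    if (!is.null(cs$grid_dims)) cs$grid_dims <- unlist(cs$grid_dims)
    args$cohort_spec <- do.call(cohort_spec, cs)
  }
  if (!is.null(y$preprocess))
    args$preprocess <- do.call(preprocess_config, y$preprocess)
  do.call(pipeline_config, args)
}

# deterministic fan-out of one top-level seed into per-stage child seeds
stage_seeds <- function(rng_seed, n = 8L) {
  with_local_seed(rng_seed, sample.int(.Machine$integer.max - 1024L, n))
}

#' Run the full synchrony pipeline on a simulated cohort
#'
#' Stages, in order: simulate cohort -> motion screening (subjects breaching
#' the limits are dropped and logged) -> temporal preprocessing -> per-subject
#' ReHo maps (normalised, smoothed) -> covariate-adjusted ReHo group contrast
#' with Monte-Carlo cluster correction -> positive clusters become seeds ->
#' per-subject, per-seed Fisher-z connectivity maps (on smoothed,
#' nuisance-regressed series; 6 motion parameters + global/WM/CSF signals) ->
#' per-group one-sample tests whose surviving clusters define the test mask
#' -> two-sample connectivity contrast within the mask -> patients'
#' cluster-mean z correlated with clinical scores (simple and partial,
#' Bonferroni-adjusted).  Identical config + seed gives identical outputs.
#'
#' @param config a [pipeline_config()] or a YAML path for
#'   [read_pipeline_config()].
#' @param out_dir optional output directory; when given, t-maps (NIfTI),
#'   cluster tables (TSV), the correlation table (TSV) and a JSON run
#'   manifest are written.
#' @return List of class `pipeline_run`: `subjects`, `excluded`,
#'   `reho_stat`, `reho_clusters`, `min_extent_reho`, `seeds`,
#'   `connectivity` (per-seed list with one-sample maps, mask, two-sample
#'   stat, clusters, min_extent), `correlations` (tibble or NULL), and
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- stage_seeds(config$rng_seed, 8L)
  cs <- config$cohort_spec
  cs$rng_seed <- seeds[1]
  pp <- config$preprocess

  cohort <- generate_cohort(cs)
  grid <- cohort$grid
  mask <- cohort$mask

  # --- motion screening -----------------------------------------------------
  screen <- vapply(cohort$motion, function(m)
    motion_screen(m, pp$motion_limit_mm, pp$motion_limit_deg)$included,
    logical(1))
  excluded <- names(screen)[!screen]
  keep <- cohort$subjects$subject_id[screen[cohort$subjects$subject_id]]
  subjects <- cohort$subjects[cohort$subjects$subject_id %in% keep, ]

  # --- preprocessing (ReHo branch) and ReHo maps ---------------------------
  reho_maps <- vector("list", length(keep))
  conn_series <- vector("list", length(keep))
  names(reho_maps) <- names(conn_series) <- keep
  for (id in keep) {
    base <- preprocess_series(cohort$series[[id]], pp,
                              smooth = pp$smooth_before_reho)
    rm_ <- reho_map(base, config$neighbourhood)
    rm_ <- normalize_global_mean(rm_)
    if (pp$smooth_fwhm_mm > 0) rm_ <- smooth_map(rm_, pp$smooth_fwhm_mm)
    reho_maps[[id]] <- rm_$values
    # connectivity branch: smooth the series, regress 9 nuisance signals
    sm <- if (pp$smooth_fwhm_mm > 0 && !pp$smooth_before_reho)
      spatial_smooth(base, pp$smooth_fwhm_mm) else base
    nt <- n_volumes(sm)
    regress <- cbind(as.matrix(cohort$motion[[id]])[(pp$n_discard + 1):(pp$n_discard + nt), ],
                     cohort$truth$nuisance[[id]][(pp$n_discard + 1):(pp$n_discard + nt), ])
    conn_series[[id]] <- regress_nuisance(sm, regress)
  }

  # --- ReHo group contrast --------------------------------------------------
  design <- make_design(subjects, config$covariates)
  reho_stat <- glm_contrast_tmap(reho_maps, design, mask = mask, grid = grid)
  fwhm_reho <- estimate_fwhm(reho_stat$residuals, grid, mask)$fwhm_mm
  min_extent_reho <- alphasim_min_extent(
    mask, grid, fwhm_reho, config$p_voxel, config$alpha, "two",
    config$connectivity, config$n_iterations, rng_seed = seeds[2])
  reho_clusters <- extract_clusters(reho_stat, config$p_voxel,
                                    min_extent_reho, config$connectivity)
  seed_rois <- if (nrow(reho_clusters) &&
                   any(reho_clusters$sign == "positive"))
    seeds_from_clusters(reho_clusters) else list()

  # --- per-seed connectivity ------------------------------------------------
  pat <- subjects$subject_id[subjects$group == "patient"]
  ctl <- subjects$subject_id[subjects$group == "control"]
  conn_results <- list()
  cluster_means <- list()
  for (k in seq_along(seed_rois)) {
    roi <- seed_rois[[k]]
    zmaps <- lapply(conn_series, function(s)
      seed_correlation_map(s, roi)$z_values)
    one_sample <- function(idset) {
      X <- matrix(1, length(idset), 1)
      glm_contrast_tmap(zmaps[idset], X, contrast = 1, mask = mask,
                        grid = grid)
    }
    st_a <- one_sample(pat)
    st_b <- one_sample(ctl)
    fw_a <- estimate_fwhm(st_a$residuals, grid, mask)$fwhm_mm
    me_one <- alphasim_min_extent(mask, grid, fw_a, config$p_voxel,
                                  config$alpha, "two", config$connectivity,
                                  config$n_iterations,
                                  rng_seed = seeds[3] + k)
    cmask <- build_connectivity_mask(st_a, st_b, config$p_voxel, me_one,
                                     config$connectivity)
    if (!any(cmask)) {
      conn_results[[roi$roi_id]] <- list(roi = roi, mask = cmask,
                                         clusters = NULL, skipped = TRUE)
      next
    }
    two <- glm_contrast_tmap(zmaps[subjects$subject_id], design,
                             mask = cmask, grid = grid)
    fw2 <- estimate_fwhm(two$residuals, grid, cmask)$fwhm_mm
    me_two <- alphasim_min_extent(cmask, grid, fw2, config$p_voxel,
                                  config$alpha, "two", config$connectivity,
                                  config$n_iterations,
                                  rng_seed = seeds[4] + k)
    cl <- extract_clusters(two, config$p_voxel, me_two, config$connectivity)
    conn_results[[roi$roi_id]] <- list(
      roi = roi, one_sample_patient = st_a, one_sample_control = st_b,
      mask = cmask, stat = two, clusters = cl, min_extent = me_two,
      skipped = FALSE)
    # patients' mean z inside each surviving cluster, for correlation
    for (j in seq_len(nrow(cl))) {
      vox <- cl$voxels[[j]]
      lin <- vox[, 1] + grid$dims[1] * (vox[, 2] - 1L) +
        prod(grid$dims[1:2]) * (vox[, 3] - 1L)
      cname <- sprintf("%s_cl%d", roi$roi_id, cl$cluster_id[j])
      cluster_means[[cname]] <- vapply(pat, function(id)
        mean(zmaps[[id]][lin]), numeric(1))
    }
  }

  # --- brain-behaviour correlation -----------------------------------------
  correlations <- NULL
  if (length(cluster_means)) {
    pat_tab <- subjects[subjects$group == "patient", ]
    # partial correlations need n >= k + 3 patients
    cov_use <- if (nrow(pat_tab) >= length(config$covariates) + 3)
      config$covariates else NULL
    correlations <- correlate_clusters_with_scores(
      as.data.frame(cluster_means), pat_tab,
      scores = config$scores, covariates = cov_use)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("rehoconn")),
    rng_seed = config$rng_seed, stage_seeds = seeds,
    n_subjects_simulated = nrow(cohort$subjects),
    n_excluded_motion = length(excluded), excluded = excluded,
    n_analyzed = nrow(subjects),
    p_voxel = config$p_voxel, alpha = config$alpha,
    connectivity = config$connectivity,
    neighbourhood = config$neighbourhood,
    band_hz = c(pp$band_low_hz, pp$band_high_hz),
    smooth_fwhm_mm = pp$smooth_fwhm_mm,
    n_discard = pp$n_discard,
    covariates = config$covariates,
    min_extent_reho = as.integer(min_extent_reho),
    n_reho_clusters = nrow(reho_clusters),
    n_seeds = length(seed_rois),
    seeds_skipped = names(Filter(function(x) isTRUE(x$skipped), conn_results)))

  run <- structure(list(subjects = subjects, excluded = excluded,
                        cohort = cohort, reho_maps = reho_maps,
                        reho_stat = reho_stat,
                        reho_clusters = reho_clusters,
                        min_extent_reho = as.integer(min_extent_reho),
                        seeds = seed_rois, connectivity = conn_results,
                        cluster_means = cluster_means,
                        correlations = correlations, manifest = manifest,
                        config = config),
                   class = "pipeline_run")
  if (!is.null(out_dir)) write_pipeline_outputs(run, out_dir)
  run
}

# write t-maps, cluster tables, correlation table and the manifest
write_pipeline_outputs <- function(run, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create ", out_dir)
  grid <- run$reho_stat$grid
  save_map(run$reho_stat$t_values, grid,
           file.path(out_dir, "reho_tmap.nii.gz"))
  write_cluster_table(run$reho_clusters,
                      file.path(out_dir, "reho_clusters.tsv"))
  for (nm in names(run$connectivity)) {
    cr <- run$connectivity[[nm]]
    if (isTRUE(cr$skipped) || is.null(cr$clusters)) next
    save_map(cr$stat$t_values, grid,
             file.path(out_dir, sprintf("conn_%s_tmap.nii.gz", nm)))
    write_cluster_table(cr$clusters,
                        file.path(out_dir, sprintf("conn_%s_clusters.tsv", nm)))
  }
  if (!is.null(run$correlations)) {
    ct <- run$correlations
    ct$covariates <- vapply(ct$covariates, paste, character(1), collapse = ",")
    utils::write.table(as.data.frame(ct),
                       file.path(out_dir, "correlations.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf(paste0("<pipeline_run> %d analyzed (%d excluded for motion), ",
                     "%d ReHo clusters (min extent %d), %d seeds\n"),
              nrow(x$subjects), length(x$excluded), nrow(x$reho_clusters),
              x$min_extent_reho, length(x$seeds)))
  if (!is.null(x$correlations)) {
    cat("top brain-behaviour correlations:\n")
    ord <- order(x$correlations$p_two_sided)
    print(utils::head(x$correlations[ord, c("cluster", "score", "kind", "r",
                                            "p_two_sided", "p_adjusted")], 4))
  }
  invisible(x)
}
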