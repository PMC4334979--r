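Package: rehoconn
Title: Regional Homogeneity and Seed-Based Connectivity Analysis of
    Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for resting-state 4D BOLD data combining
    intraregional synchrony (regional homogeneity via Kendall's coefficient
    of concordance over 27-voxel neighborhoods) with interregional synchrony
    (seed-based voxelwise Pearson correlation and Fisher z maps).  Includes
    temporal preprocessing (volume discarding, linear detrending, ideal
    band-pass filtering, Gaussian smoothing, nuisance regression), motion
    screening, covariate-adjusted voxelwise group inference with Monte-Carlo
    cluster-extent correction, data-driven seed selection from group
    contrasts, and brain-behavior correlation of cluster summaries against
    clinical severity scores with Bonferroni control.  A synthetic two-group
    cohort generator with planted local-synchrony and seed-to-remote coupling
    effects provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
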