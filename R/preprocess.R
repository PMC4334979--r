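#' Drop initial (dummy) volumes from a series
#'
#' Scanner equilibration volumes at the start of a run are conventionally
#' discarded before analysis; a 240-volume acquisition with `n = 10` leaves
#' the 230 analysed volumes.
#'
#' @param series a [bold_series()].
#' @param n number of leading volumes to remove (`0 <= n < n_volumes`).
#' @return The shortened [bold_series()].
#' @export
discard_initial_volumes <- function(series, n) {
  nt <- n_volumes(series)
  n <- as.integer(n)
  if (n < 0L) stop("`n` must be nonnegative")
  if (n >= nt) stop("cannot discard ", n, " of ", nt, " volumes")
  if (n == 0L) return(series)
  series$data <- series$data[, , , -(seq_len(n)), drop = FALSE]
  series
}

#' Screen a subject's head motion against exclusion limits
#'
#' A subject is excluded when any translation exceeds `limit_mm` or any
#' rotation exceeds `limit_deg` in absolute value, on any axis.  "Exceeds"
#' is strict: a maximum of exactly 2.0 mm is retained under the default
#' 2.0 mm limit.
#'
#' @param motion motion table (6 numeric columns: 3 translations in mm,
#'   3 rotations in degrees; one row per volume), e.g. from
#'   [read_motion_params()].
#' @param limit_mm,limit_deg exclusion limits (defaults 2.0 mm, 2.0 deg).
#' @return List with `included` (logical) and `max_abs` (named 6-vector of
#'   per-column maximum absolute motion).
#' @export
motion_screen <- function(motion, limit_mm = 2, limit_deg = 2) {
  m <- as.matrix(as.data.frame(motion))
  if (nrow(m) == 0L) stop("motion table is empty")
  if (ncol(m) != 6L) stop("motion table must have 6 columns")
  max_abs <- apply(abs(m), 2, max)
  names(max_abs) <- c("trans_x", "trans_y", "trans_z",
                      "rot_x", "rot_y", "rot_z")
  list(included = all(max_abs[1:3] <= limit_mm) && all(max_abs[4:6] <= limit_deg),
       max_abs = max_abs)
}

# residual-making projection applied column-wise to a time x voxel matrix
project_out <- function(mat, design) {
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) stop("rank-deficient design")
  qr.resid(qrd, mat)
}

#' Remove per-voxel linear trends
#'
#' Fits intercept + slope over time to every voxel series by least squares
#' and subtracts the fit; residuals have zero mean and are orthogonal to the
#' linear ramp.
#'
#' @param series a [bold_series()] with at least 3 volumes.
#' @return The detrended [bold_series()].
#' @export
linear_detrend <- function(series) {
  nt <- n_volumes(series)
  if (nt < 3L) stop("need at least 3 volumes to detrend")
  X <- cbind(1, seq_len(nt) - (nt + 1) / 2)
  matrix_to_series(project_out(series_matrix(series), X), series)
}

#' Ideal (discrete-Fourier) band-pass filter
#'
#' Transforms each voxel series to the frequency domain, retains exactly the
#' DFT bins whose frequency lies in `[low_hz, high_hz]` (zeroing all others,
#' including DC), and inverts.  The operation is an exact projection:
#' applying it twice equals applying it once.
#'
#' @param series a [bold_series()].
#' @param low_hz,high_hz passband edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < 1/(2 * tr_s)` (defaults 0.01 and 0.08, the
#'   conventional resting-state band).
#' @return The filtered [bold_series()].
#' @export
bandpass_filter <- function(series, low_hz = 0.01, high_hz = 0.08) {
  tr <- series$tr_s
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < 1 / (2 * tr)))
    stop("band must satisfy 0 < low < high < Nyquist (", 1 / (2 * tr), " Hz)")
  nt <- n_volumes(series)
  f <- (seq_len(nt) - 1) / (nt * tr)        # bin frequencies, 0 .. (nt-1)/(nt*tr)
  f_fold <- pmin(f, 1 / tr - f)             # |frequency| each bin represents
  keep <- f_fold >= low_hz & f_fold <= high_hz
  mat <- series_matrix(series)
  ft <- stats::mvfft(mat)
  ft[!keep, ] <- 0
  matrix_to_series(Re(stats::mvfft(ft, inverse = TRUE)) / nt, series)
}

# 1D Gaussian convolution matrix (rows renormalised at the edges so each
# output voxel is a unit-weight average of available neighbours)
gauss_axis_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  i <- seq_len(n)
  K <- exp(-outer(i, i, "-")^2 / (2 * sigma_vox^2))
  K[abs(outer(i, i, "-")) > ceiling(4 * sigma_vox)] <- 0
  K / rowSums(K)
}

# smooth the first three dims of a (x,y,z[,m]) array with per-axis sigmas
smooth_stack <- function(arr, sigmas_vox) {
  d <- dim(arr)
  if (length(d) == 3L) d <- c(d, 1L)
  a <- array(arr, dim = d)
  M1 <- gauss_axis_matrix(d[1], sigmas_vox[1])
  M2 <- gauss_axis_matrix(d[2], sigmas_vox[2])
  M3 <- gauss_axis_matrix(d[3], sigmas_vox[3])
  a <- array(M1 %*% matrix(a, d[1]), dim = d)
  a <- aperm(array(M2 %*% matrix(aperm(a, c(2, 1, 3, 4)), d[2]),
                   dim = d[c(2, 1, 3, 4)]), c(2, 1, 3, 4))
  a <- aperm(array(M3 %*% matrix(aperm(a, c(3, 1, 2, 4)), d[3]),
                   dim = d[c(3, 1, 2, 4)]), c(2, 3, 1, 4))
  array(a, dim = dim(arr))
}

#' Separable Gaussian spatial smoothing
#'
#' Smooths a 3D field, a 4D array, or every volume of a [bold_series()]
#' with a separable Gaussian kernel of the given full width at half maximum
#' (per-axis sigma `fwhm / (2 sqrt(2 ln 2))` in mm, converted to voxels).
#' `fwhm_mm = 0` is the identity.  When `mask` is supplied, smoothing is
#' mask-normalised: the field is zero-filled outside the mask, smoothed, and
#' divided by the smoothed mask indicator, so in-mask values are unbiased
#' near the brain edge; outside-mask voxels are set to NaN.
#'
#' @param x 3D/4D numeric array or a [bold_series()].
#' @param fwhm_mm kernel FWHM in mm (scalar or per-axis; >= 0).
#' @param grid a [volume_grid()] (ignored when `x` is a series).
#' @param mask optional 3D logical array for mask-normalised smoothing.
#' @return Object of the same shape/class as `x`.
#' @export
spatial_smooth <- function(x, fwhm_mm, grid = NULL, mask = NULL) {
  if (any(fwhm_mm < 0)) stop("`fwhm_mm` must be nonnegative")
  if (inherits(x, "bold_series")) {
    x$data <- spatial_smooth(x$data, fwhm_mm, x$grid, mask)
    return(x)
  }
  if (is.null(grid)) stop("`grid` required for array input")
  fw <- rep(as.numeric(fwhm_mm), length.out = 3L)
  if (all(fw == 0)) return(x)
  sig <- fw / (2 * sqrt(2 * log(2))) / grid$voxel_size_mm
  if (is.null(mask)) return(smooth_stack(x, sig))
  d <- dim(x)
  nt <- if (length(d) == 4L) d[4] else 1L
  xm <- array(x, dim = c(d[1:3], nt))
  xm[!rep(mask, nt)] <- 0
  sm <- smooth_stack(xm, sig)
  w <- smooth_stack(array(as.numeric(mask), dim = grid$dims), sig)
  out <- sweep(sm, 1:3, w, "/")
  out[!rep(mask, nt)] <- NaN
  array(out, dim = d)
}

#' Regress nuisance signals out of every voxel series
#'
#' Removes, per voxel, the least-squares fit on an intercept plus the given
#' per-volume regressors (canonically 6 rigid-motion parameters and the
#' global, white-matter and CSF mean signals, 9 columns).  Residuals are
#' orthogonal to every regressor, and no voxel's variance can increase.
#'
#' @param series a [bold_series()].
#' @param regressors numeric matrix, one row per volume, one column per
#'   nuisance signal; columns must be linearly independent of each other and
#'   of the intercept.
#' @return The residual [bold_series()].
#' @export
regress_nuisance <- function(series, regressors) {
  R <- as.matrix(regressors)
  if (nrow(R) != n_volumes(series))
    stop("regressor rows (", nrow(R), ") must equal volume count (",
         n_volumes(series), ")")
  if (ncol(R) > 0)   # all-zero columns carry no signal; keep the intercept fit
    R <- R[, colSums(R != 0) > 0, drop = FALSE]
  X <- cbind(1, R)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient nuisance design")
  matrix_to_series(project_out(series_matrix(series), X), series)
}

#' Preprocessing settings
#'
#' Bundles the temporal/spatial conditioning parameters with the
#' conventional defaults: discard 10 volumes, band-pass 0.01-0.08 Hz,
#' 4 mm FWHM smoothing, 2.0 mm / 2.0 degree motion limits.
#'
#' @param n_discard leading volumes to drop.
#' @param band_low_hz,band_high_hz passband in Hz.
#' @param smooth_fwhm_mm Gaussian FWHM in mm (0 disables smoothing).
#' @param motion_limit_mm,motion_limit_deg exclusion limits.
#' @param smooth_before_reho if TRUE the series itself is smoothed before
#'   ReHo (double smoothing); the default computes ReHo on unsmoothed data
#'   and smooths the ReHo map afterwards.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(n_discard = 10, band_low_hz = 0.01,
                              band_high_hz = 0.08, smooth_fwhm_mm = 4,
                              motion_limit_mm = 2, motion_limit_deg = 2,
                              smooth_before_reho = FALSE) {
  stopifnot(n_discard >= 0, band_low_hz > 0, band_high_hz > band_low_hz,
            smooth_fwhm_mm >= 0)
  structure(list(n_discard = n_discard, band_low_hz = band_low_hz,
                 band_high_hz = band_high_hz, smooth_fwhm_mm = smooth_fwhm_mm,
                 motion_limit_mm = motion_limit_mm,
                 motion_limit_deg = motion_limit_deg,
                 smooth_before_reho = smooth_before_reho),
            class = "preprocess_config")
}

#' Run the temporal preprocessing chain on one series
#'
#' Applies discard -> linear detrend -> band-pass in order.  Optional
#' smoothing and nuisance regression are applied afterwards when requested
#' (the connectivity branch smooths and regresses; the regional-homogeneity
#' branch stops at the filter and smooths the resulting map instead).
#'
#' @param series a [bold_series()].
#' @param config a [preprocess_config()].
#' @param smooth apply spatial smoothing after filtering.
#' @param regressors optional nuisance matrix (rows must match the volume
#'   count *after* discarding) passed to [regress_nuisance()].
#' @return The preprocessed [bold_series()].
#' @export
preprocess_series <- function(series, config = preprocess_config(),
                              smooth = FALSE, regressors = NULL) {
  s <- discard_initial_volumes(series, config$n_discard)
  s <- linear_detrend(s)
  s <- bandpass_filter(s, config$band_low_hz, config$band_high_hz)
  if (smooth && config$smooth_fwhm_mm > 0)
    s <- spatial_smooth(s, config$smooth_fwhm_mm)
  if (!is.null(regressors)) s <- regress_nuisance(s, regressors)
  s
}
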