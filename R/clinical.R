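#' Pearson correlation with t-based p-value
#'
#' `t = r sqrt(n-2) / sqrt(1-r^2)` on `n - 2` degrees of freedom, two-sided.
#'
#' @param x,y numeric vectors of equal length (n >= 3, nonzero variance).
#' @return One-row tibble: `r`, `n`, `dof`, `t_stat`, `p_two_sided`,
#'   `kind = "pearson"`.
#' @export
pearson_r_p <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  n <- length(x)
  if (n < 3L) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  r <- stats::cor(x, y)
  correlation_result(r, n, k = 0L, kind = "pearson")
}

#' p-value implied by a correlation coefficient and sample size
#'
#' Useful for checking printed r/p pairs: the two-sided p of the t statistic
#' `r sqrt(dof) / sqrt(1 - r^2)` on `dof = n - 2 - k` degrees of freedom.
#'
#' @param r correlation coefficient.
#' @param n sample size.
#' @param k number of partialled covariates (0 for simple Pearson).
#' @return Two-sided p-value.
#' @export
#' @examples
#' pearson_p_from_r(0.459, 29)   # ~0.012
pearson_p_from_r <- function(r, n, k = 0L) {
  dof <- n - 2L - k
  if (dof < 1L) stop("nonpositive degrees of freedom")
  t <- r * sqrt(dof) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t), dof)
}

correlation_result <- function(r, n, k, kind, covariates = character()) {
  dof <- n - 2L - k
  t <- if (abs(r) >= 1) sign(r) * Inf else r * sqrt(dof) / sqrt(1 - r^2)
  tibble::tibble(r = r, n = as.integer(n), dof = as.integer(dof), t_stat = t,
                 p_two_sided = 2 * stats::pt(-abs(t), dof),
                 kind = kind, covariates = list(covariates))
}

#' Partial correlation controlling for covariates
#'
#' Residualises `x` and `y` on an intercept plus the covariate matrix and
#' correlates the residuals; `dof = n - 2 - k` for `k` covariates.  With no
#' covariates this reduces exactly to [pearson_r_p()].
#'
#' @param x,y numeric vectors.
#' @param covariates n x k numeric matrix/data frame (k may be 0).
#' @return One-row tibble as in [pearson_r_p()] with `kind = "partial"`.
#' @export
partial_corr_r_p <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("length mismatch")
  C <- if (is.null(covariates)) matrix(nrow = n, ncol = 0) else {
    cm <- as.matrix(as.data.frame(covariates))
    storage.mode(cm) <- "double"
    cm
  }
  k <- ncol(C)
  if (n < k + 3L) stop("need n >= k + 3")
  X <- cbind(1, C)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) stop("rank-deficient covariates")
  rx <- qr.resid(qrx, x)
  ry <- qr.resid(qrx, y)
  # a variable that is an exact linear function of the covariates leaves only
  # rounding noise; its partial correlation is 0 by definition
  tiny <- function(r, v) stats::sd(r) <= 1e-10 * max(stats::sd(v), 1e-300)
  if (tiny(rx, x) || tiny(ry, y))
    return(correlation_result(0, n, k, kind = if (k > 0) "partial" else "pearson",
                              covariates = colnames(C) %||% character()))
  correlation_result(stats::cor(rx, ry), n, k,
                     kind = if (k > 0) "partial" else "pearson",
                     covariates = colnames(C) %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)` for a family of `m` tests.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param m family size (>= number of tests; default `length(p_values)`).
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  if (m < length(p_values)) stop("m must be >= number of tests")
  pmin(1, m * p_values)
}

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance (Student) two-sample t from group means, SDs and sizes,
#' `dof = n1 + n2 - 2`; set `welch = TRUE` for the unequal-variance version.
#' Useful for checking demographic tables that print only summaries.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries (sd > 0, n >= 2).
#' @param welch use Welch's approximation instead of pooling.
#' @return List with `t`, `dof`, `p` (two-sided).
#' @export
summary_two_sample_t <- function(mean1, sd1, n1, mean2, sd2, n2,
                                 welch = FALSE) {
  if (sd1 <= 0 || sd2 <= 0) stop("sds must be positive")
  if (n1 < 2 || n2 < 2) stop("ns must be >= 2")
  if (welch) {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    t <- (mean1 - mean2) / sqrt(se2)
    dof <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    dof <- n1 + n2 - 2
  }
  list(t = t, dof = dof, p = 2 * stats::pt(-abs(t), dof))
}

#' Pearson chi-square test for a 2x2 table
#'
#' Uncorrected (no Yates continuity correction), 1 degree of freedom:
#' `chi2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`.
#'
#' @param a,b,c,d cell counts, row-wise: `rbind(c(a, b), c(c, d))`.
#' @return List with `chi2`, `dof = 1`, `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be nonnegative")
  N <- a + b + c + d
  marg <- c(a + b, c + d, a + c, b + d)
  if (any(marg == 0)) stop("zero marginal total")
  chi2 <- N * (a * d - b * c)^2 / prod(marg)
  list(chi2 = chi2, dof = 1L, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

#' Correlate cluster summaries with clinical scores
#'
#' For every (cluster, score) pair, computes the simple Pearson correlation
#' and (when covariates are given) the partial correlation controlling for
#' them, with Bonferroni adjustment over the family
#' `m = n_clusters x n_scores` within each kind.
#'
#' @param cluster_values data frame/tibble of per-subject cluster summaries
#'   (one column per cluster, e.g. mean ReHo or mean z within the cluster),
#'   rows aligned with `subjects`.
#' @param subjects subject table holding the score and covariate columns
#'   (typically patients only; rows with missing scores are dropped
#'   pairwise).
#' @param scores character vector of score column names (default THQ, SAS,
#'   SDS, duration).
#' @param covariates character vector of covariate column names for the
#'   partial variant (NULL for simple only).
#' @return Tibble with one row per (cluster, score, kind): `cluster`,
#'   `score`, `kind`, `r`, `n`, `dof`, `t_stat`, `p_two_sided`, `p_adjusted`.
#' @export
correlate_clusters_with_scores <- function(cluster_values, subjects,
                                           scores = c("thq", "sas", "sds",
                                                      "duration_months"),
                                           covariates = c("age_years", "sex",
                                                          "education_years",
                                                          "gm_volume_ml")) {
  cluster_values <- as.data.frame(cluster_values)
  subjects <- as.data.frame(subjects)
  if (ncol(cluster_values) == 0L) stop("no clusters supplied")
  if (nrow(cluster_values) != nrow(subjects)) stop("row mismatch")
  scores <- intersect(scores, names(subjects))
  if (!length(scores)) stop("no score columns found")
  m <- ncol(cluster_values) * length(scores)
  rows <- list()
  for (cl in names(cluster_values)) {
    for (sc in scores) {
      y <- subjects[[sc]]
      ok <- !is.na(y) & !is.na(cluster_values[[cl]])
      if (sum(ok) < 3L) stop("too few non-missing scores for ", sc)
      if (stats::sd(y[ok]) == 0) stop("score ", sc, " has zero variance")
      x <- cluster_values[[cl]][ok]
      res <- pearson_r_p(x, y[ok])
      res$cluster <- cl
      res$score <- sc
      rows[[length(rows) + 1L]] <- res
      if (!is.null(covariates)) {
        C <- subjects[ok, covariates, drop = FALSE]
        if (any(vapply(C, is.character, TRUE)))
          C[] <- lapply(C, function(v)
            if (is.character(v) || is.factor(v)) as.integer(factor(v)) - 1L else v)
        resp <- partial_corr_r_p(x, y[ok], C)
        resp$kind <- "partial"
        resp$cluster <- cl
        resp$score <- sc
        rows[[length(rows) + 1L]] <- resp
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- NA_real_
  for (kd in unique(out$kind))
    out$p_adjusted[out$kind == kd] <-
      bonferroni_adjust(out$p_two_sided[out$kind == kd], m)
  cols <- c("cluster", "score", "kind", "r", "n", "dof", "t_stat",
            "p_two_sided", "p_adjusted")
  tibble::as_tibble(out[, c(cols, setdiff(names(out), cols))])
}
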