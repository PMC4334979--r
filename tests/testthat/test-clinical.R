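test_that("pearson_r_p recovers exact linear association and matches cor.test", {
  x <- c(1, 3, 4, 7, 9, 12)
  expect_equal(pearson_r_p(x, 2 * x + 1)$r, 1)
  set.seed(61)
  a <- rnorm(25); b <- 0.4 * a + rnorm(25)
  got <- pearson_r_p(a, b)
  ct <- cor.test(a, b)
  expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(got$p_two_sided, ct$p.value, tolerance = 1e-12)
  expect_equal(got$dof, 23L)
  expect_error(pearson_r_p(a, rep(1, 25)), "zero variance")
  expect_error(pearson_r_p(a, b[1:10]), "mismatch")
})

test_that("printed headline r/p pairs are internally consistent at dof = n - 2", {
  expect_equal(round(pearson_p_from_r(0.459, 29), 3), 0.012)
  expect_equal(round(pearson_p_from_r(0.479, 29), 3), 0.009)
  # p is monotone decreasing in |r| and in n
  rs <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(diff(sapply(rs, pearson_p_from_r, n = 29)) < 0))
  ns <- c(10, 20, 40, 80)
  expect_true(all(diff(sapply(ns, function(n) pearson_p_from_r(0.3, n))) < 0))
})

test_that("partial correlation reduces to Pearson and matches the
           residualisation oracle", {
  set.seed(71)
  n <- 40
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  expect_equal(partial_corr_r_p(x, y)$r, pearson_r_p(x, y)$r,
               tolerance = 1e-12)
  C <- cbind(rnorm(n), rnorm(n), runif(n))
  xs <- x + 2 * C[, 1] - C[, 3]
  ys <- y - C[, 1] + 0.5 * C[, 2]
  got <- partial_corr_r_p(xs, ys, C)
  # oracle: explicit normal equations
  H <- cbind(1, C)
  beta_x <- solve(t(H) %*% H, t(H) %*% xs)
  beta_y <- solve(t(H) %*% H, t(H) %*% ys)
  r_oracle <- cor(xs - H %*% beta_x, ys - H %*% beta_y)
  expect_equal(got$r, as.numeric(r_oracle), tolerance = 1e-10)
  expect_equal(got$dof, n - 2L - 3L)
  # y identical to a covariate -> partial r ~ 0
  same <- partial_corr_r_p(xs, C[, 1] + 0, C)
  expect_lt(abs(same$r), 1e-10)
  expect_error(partial_corr_r_p(x, y, cbind(C[, 1], C[, 1])), "rank")
})

test_that("bonferroni_adjust multiplies, caps, and never decreases", {
  expect_equal(bonferroni_adjust(0.01, 5), 0.05)
  expect_equal(bonferroni_adjust(0.5, 3), 1)
  expect_equal(bonferroni_adjust(c(0.2, 0.04), 2), c(0.4, 0.08))
  p <- runif(10)
  expect_true(all(bonferroni_adjust(p, 10) >= p))
  expect_equal(bonferroni_adjust(p[1], 1), p[1])
  expect_error(bonferroni_adjust(1.2, 2), "\\[0, 1\\]")
  expect_error(bonferroni_adjust(c(0.1, 0.2), 1), ">=")
})

test_that("summary t-test reproduces demographic-table p values from summaries", {
  # age row: 40.9 +/- 10.5 (n 29) vs 46.2 +/- 11.9 (n 30)
  age <- summary_two_sample_t(40.9, 10.5, 29, 46.2, 11.9, 30)
  expect_lt(abs(age$p - 0.074), 0.01)
  expect_equal(age$dof, 57)
  # gray matter row: 581.2 +/- 26.4 vs 576.1 +/- 22.1
  gm <- summary_two_sample_t(581.2, 26.4, 29, 576.1, 22.1, 30)
  expect_lt(abs(gm$p - 0.423), 0.01)
  # white matter row: 531.6 +/- 25.6 vs 528.8 +/- 25.4
  wm <- summary_two_sample_t(531.6, 25.6, 29, 528.8, 25.4, 30)
  expect_lt(abs(wm$p - 0.680), 0.01)
  # equal means -> t = 0, p = 1
  eq <- summary_two_sample_t(5, 1, 10, 5, 1.5, 12)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  # cross-check pooled t against t.test on data with those exact summaries
  set.seed(81)
  g1 <- rnorm(29); g1 <- (g1 - mean(g1)) / sd(g1) * 10.5 + 40.9
  g2 <- rnorm(30); g2 <- (g2 - mean(g2)) / sd(g2) * 11.9 + 46.2
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(age$t, unname(tt$statistic), tolerance = 1e-10)
  expect_error(summary_two_sample_t(1, 0, 5, 2, 1, 5), "positive")
})

test_that("uncorrected chi-square matches its closed form and the sex-split p", {
  sex <- chi_square_2x2(16, 13, 15, 15)
  expect_equal(round(sex$p, 3), 0.691)
  expect_equal(sex$chi2,
               59 * (16 * 15 - 13 * 15)^2 / (29 * 30 * 31 * 28),
               tolerance = 1e-12)
  bal <- chi_square_2x2(10, 10, 10, 10)
  expect_equal(bal$chi2, 0)
  expect_equal(bal$p, 1)
  # agrees with stats::chisq.test without continuity correction
  ct <- chisq.test(rbind(c(16, 13), c(15, 15)), correct = FALSE)
  expect_equal(sex$chi2, unname(ct$statistic), tolerance = 1e-12)
  expect_error(chi_square_2x2(0, 0, 3, 4), "marginal")
})

test_that("correlate_clusters_with_scores recovers a planted link and
           applies the cluster-by-score family", {
  set.seed(91)
  n <- 30
  z <- rnorm(n)
  subjects <- tibble::tibble(
    group = "patient",
    age_years = rnorm(n, 41, 10), sex = sample(c("male", "female"), n, TRUE),
    education_years = rnorm(n, 11, 2), gm_volume_ml = rnorm(n, 580, 25),
    thq = 100 + 34 * z + rnorm(n, 0, 66), sas = rnorm(n, 38, 6),
    sds = rnorm(n, 38, 6), duration_months = pmax(1, rnorm(n, 40, 30)))
  clusters <- data.frame(cl_a = 0.2 * z + rnorm(n, 0, 0.05),
                         cl_b = rnorm(n))
  res <- correlate_clusters_with_scores(clusters, subjects)
  expect_equal(nrow(res), 2 * 4 * 2)       # clusters x scores x kinds
  thq_a <- res[res$cluster == "cl_a" & res$score == "thq" &
                 res$kind == "pearson", ]
  expect_gt(thq_a$r, 0)
  # Bonferroni family is clusters x scores within each kind
  expect_equal(res$p_adjusted, pmin(1, res$p_two_sided * 8), tolerance = 1e-12)
  expect_error(correlate_clusters_with_scores(
    clusters, within(subjects, thq <- 1)), "zero variance")
  # permuted scores kill the association
  perm <- subjects
  perm$thq <- sample(perm$thq)
  res_p <- correlate_clusters_with_scores(clusters["cl_a"], perm,
                                          scores = "thq", covariates = NULL)
  expect_lt(abs(res_p$r), 0.5)
})
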