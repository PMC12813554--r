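# Spearman matrices, relevance proportions, two-proportion Z, ECDF/KS, and
# the RNA-group comparison grid.

test_that("spearman_matrix handles perfect monotone pairs and ties", {
  x <- matrix(c(1, 2, 3, 4), 1, 4, dimnames = list("p", NULL))
  y <- matrix(c(10, 20, 30, 40), 1, 4, dimnames = list("r", NULL))
  expect_equal(as.numeric(spearman_matrix(x, y)), 1)
  expect_equal(as.numeric(spearman_matrix(x, y[, 4:1, drop = FALSE])), -1)
  # average-rank tie handling, hand-computed
  xt <- matrix(c(1, 2, 2, 4), 1, 4)
  yt <- matrix(c(1, 3, 2, 4), 1, 4)
  # hand-computed: ranks (1, 2.5, 2.5, 4) vs (1, 3, 2, 4) give
  # cov 4.5 / sqrt(4.5 * 5)
  expect_equal(as.numeric(spearman_matrix(xt, yt)), 4.5 / sqrt(22.5))
  expect_equal(as.numeric(spearman_matrix(xt, yt)),
               cor(c(1, 2, 2, 4), c(1, 3, 2, 4), method = "spearman"))
})

test_that("constant rows yield NA correlations with a tally", {
  x <- rbind(p1 = c(0.5, 0.5, 0.5, 0.5), p2 = c(0.1, 0.2, 0.3, 0.4))
  y <- rbind(r1 = rnorm(4), r2 = rnorm(4))
  expect_message(rho <- spearman_matrix(x, y), "constant")
  expect_true(all(is.na(rho["p1", ])))
  expect_true(all(!is.na(rho["p2", ])))
  expect_identical(attr(rho, "n_constant_rows"), 1L)
})

test_that("spearman matrices agree with stats::cor and are chunk-invariant", {
  set.seed(5)
  X <- matrix(runif(30 * 12), 30, 12, dimnames = list(paste0("p", 1:30), NULL))
  Y <- matrix(rnorm(8 * 12), 8, 12, dimnames = list(paste0("r", 1:8), NULL))
  ref <- cor(t(X), t(Y), method = "spearman")
  expect_equal(spearman_matrix(X, Y), ref, tolerance = 1e-12,
               ignore_attr = "n_constant_rows")
  expect_equal(spearman_matrix(X, Y, chunk_size = 7), ref, tolerance = 1e-12,
               ignore_attr = "n_constant_rows")
})

test_that("rank invariance: rho on beta equals rho on M exactly", {
  co <- small_cohort(seed = 2)
  beta <- co$methylation$beta[1:40, ]
  expr <- co$expression$expr[1:30, ]
  r_beta <- spearman_matrix(beta, expr)
  r_m <- spearman_matrix(beta_to_m(beta), expr)
  expect_equal(r_beta, r_m, tolerance = 1e-12)
})

test_that("proportion_relevant uses a strict threshold and excludes NA", {
  rho <- matrix(c(0.31, -0.31, 0.30, 0.29), 2, 2,
                dimnames = list(NULL, c("a", "b")))
  pr <- proportion_relevant(rho, c("a", "b"), tau = 0.3)
  expect_identical(pr$n_relevant, 2L)
  expect_equal(pr$proportion, 0.5)
  rho[1, 1] <- NA
  pr2 <- proportion_relevant(rho, c("a", "b"), tau = 0.3)
  expect_identical(pr2$n_pairs, 3L)
  expect_error(proportion_relevant(rho, character(0)), "empty")
  # group = everything equals the pooled computation
  expect_equal(proportion_relevant(rho, colnames(rho))$proportion,
               sum(abs(rho) > 0.3, na.rm = TRUE) / 3)
})

test_that("two-proportion Z matches the closed form and handles degeneracy", {
  eq <- two_proportion_ztest(5, 10, 10, 20)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  zt <- two_proportion_ztest(8, 10, 2, 10)
  expect_equal(zt$z, 2.683282, tolerance = 1e-6)
  expect_equal(zt$p, 0.0072903, tolerance = 1e-4)
  deg <- two_proportion_ztest(0, 10, 0, 10)
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
  big <- two_proportion_ztest(100000, 200000, 50000, 200000)
  expect_identical(big$p_display, "< 2.2e-16")
  expect_error(two_proportion_ztest(11, 10, 1, 10))
})

test_that("asymptotic z p-value converges toward the exact enumeration", {
  # the normal approximation error shrinks as counts grow
  d_small <- abs(two_proportion_ztest(8, 10, 2, 10)$p - oracle_ztest_enum(8, 10, 2, 10))
  d_large <- abs(two_proportion_ztest(160, 200, 40, 200)$p -
                   oracle_ztest_enum(160, 200, 40, 200))
  expect_lt(d_large, d_small)
  expect_lt(d_large, 1e-4)
})

test_that("ecdf_table is a right-continuous step from 0 to 1", {
  e <- ecdf_table(c(1, 2, 3))
  expect_equal(e$cumprop[e$value == 2], 2 / 3)
  e2 <- ecdf_table(c(1, 1, 2))
  expect_equal(e2$cumprop[e2$value == 1], 2 / 3)
  expect_equal(max(e2$cumprop), 1)
  expect_error(ecdf_table(numeric(0)), "no values")
})

test_that("KS statistic equals the brute-force ECDF maximisation", {
  same <- ks_two_sample(1:5, 1:5)
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  expect_equal(ks_two_sample(c(1, 2, 3), c(4, 5, 6))$D, 1)
  expect_equal(ks_two_sample(c(1, 3), c(2, 4))$D, 0.5)
  set.seed(11)
  for (i in 1:50) {
    a <- sample(1:8, sample(2:10, 1), replace = TRUE) + runif(1)
    b <- rnorm(sample(2:10, 1))
    expect_identical(ks_two_sample(a, b)$D, oracle_ks_d(a, b))
  }
})

test_that("DERNA labelling recovers planted signals and respects nulls", {
  co <- small_cohort(seed = 4, frac_dernas = 0.1)
  dl <- label_dernas(co$expression$expr, co$sheet)
  sens <- mean(co$truth$true_derna_ids %in% names(dl)[dl])
  expect_gte(sens, 0.8)
  # permuted group labels: approximately nothing called
  sh <- co$sheet
  set.seed(1)
  sh$group <- sample(sh$group)
  expect_lte(sum(label_dernas(co$expression$expr, sh)), 2)
  expect_identical(sum(label_dernas(co$expression$expr, co$sheet, fdr = 0)), 0L)
})

test_that("strength labelling is restricted to DERNAs", {
  co <- small_cohort(seed = 6, frac_dernas = 0.1)
  derna <- stats::setNames(co$expression$labels$derna, co$expression$labels$rna_id)
  pat <- co$sheet$group == "patient"
  sa <- label_strength_association(co$expression$expr, co$sheet$strength,
                                   derna, pat)
  expect_true(all(derna[names(sa)[sa]]))  # non-DERNA never flagged
  sens <- mean(co$truth$strength_coupled_rna_ids %in% names(sa)[sa])
  expect_gte(sens, 0.7)
  expect_error(label_strength_association(co$expression$expr,
                                          rep(1, ncol(co$expression$expr)),
                                          derna, pat), "constant")
})

test_that("compare_rna_groups produces the full grid and skips empty sides", {
  co <- small_cohort(seed = 8)
  rho <- spearman_matrix(co$methylation$beta[1:80, ], co$expression$expr)
  ce <- compare_rna_groups(rho, co$expression$labels)
  expect_s3_class(ce, "corr_enrichment")
  g <- setNames(ce$groups$n_rnas, ce$groups$group)
  expect_identical(unname(g[["derna"]] + g[["non_derna"]]), ncol(rho))
  # relevant counts aggregate across the DERNA split
  nr <- setNames(ce$groups$n_relevant, ce$groups$group)
  pooled <- sum(abs(rho) > ce$tau, na.rm = TRUE)
  expect_identical(unname(nr[["derna"]] + nr[["non_derna"]]), pooled)
  expect_true(all(ce$comparisons$group1 %in%
                    c("derna", "strength", "mitochondrial_strength",
                      "lipid_strength", "fibrosis_strength")))
  # labels all FALSE: no comparisons
  lab0 <- co$expression$labels
  lab0$derna <- FALSE; lab0$strength_associated <- FALSE; lab0$pathway <- "none"
  expect_message(ce0 <- compare_rna_groups(rho, lab0), "skipped")
  expect_null(ce0$comparisons)
})
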