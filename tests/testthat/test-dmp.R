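# Per-probe covariate-adjusted models, BH adjustment and DMP calling.

test_that("noiseless group effect is recovered exactly", {
  sheet <- toy_sheet(8, group = rep(c("patient", "control"), each = 4))
  M <- matrix(1.0 + 0.5 * as.numeric(sheet$group == "patient"), 1, 8,
              dimnames = list("cg1", sheet$sample_id))
  fit <- fit_dmp_models(M, sheet)
  expect_equal(fit$delta_m, 0.5, tolerance = 1e-10)
  expect_lt(fit$p_value, 1e-12)
  expect_identical(fit$df, 8L - 5L)
})

test_that("a group difference explained by age is adjusted away", {
  # closed-form check on a hand-built design: M depends on age only, but the
  # groups differ in mean age, so the unadjusted group contrast is biased
  sheet <- toy_sheet(8, group = rep(c("patient", "control"), each = 4),
                     age = c(60, 62, 64, 66, 40, 42, 44, 46),
                     sex = rep(c("male", "female"), 4),
                     bmi = c(24, 27, 25, 31, 26, 23, 28, 24.5))
  M <- matrix(0.1 * sheet$age, 1, 8, dimnames = list("cg1", sheet$sample_id))
  fit <- fit_dmp_models(M, sheet)
  expect_equal(fit$delta_m, 0, tolerance = 1e-10)
  naive <- mean(M[1, 1:4]) - mean(M[1, 5:8])
  expect_gt(naive, 1.9)  # the unadjusted contrast is large
})

test_that("pure-noise probes give approximately uniform p-values", {
  set.seed(42)
  n <- 60
  sheet <- toy_sheet(n, group = rep(c("patient", "control"), c(40, 20)),
                     age = round(rnorm(n, 55, 8)),
                     bmi = round(rnorm(n, 26, 3), 1))
  M <- matrix(rnorm(1000 * n), 1000, n,
              dimnames = list(sprintf("cg%04d", 1:1000), sheet$sample_id))
  fit <- fit_dmp_models(M, sheet)
  frac <- mean(fit$p_value < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
  expect_gt(suppressWarnings(ks.test(fit$p_value, "punif")$p.value), 0.001)
})

test_that("rank-deficient designs and missing covariates are rejected", {
  sheet <- toy_sheet(8, group = rep(c("patient", "control"), each = 4))
  sheet$bmi <- sheet$age  # collinear
  M <- matrix(rnorm(8), 1, 8, dimnames = list("cg1", sheet$sample_id))
  expect_error(fit_dmp_models(M, sheet), "collinear|rank deficient")
  sheet2 <- toy_sheet(8, group = rep(c("patient", "control"), each = 4))
  sheet2$age[3] <- NA
  expect_error(fit_dmp_models(M, sheet2), "age")
})

test_that("bh_adjust matches the literal step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.5)), c(0.01, 0.5))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(7)
  for (i in 1:25) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("call_dmps fills direction, effect size and summary consistently", {
  co <- small_cohort(seed = 21)
  ds <- filter_snp_probes(filter_probes_by_detection(co$methylation),
                          co$annotation)
  fit <- fit_dmp_models(beta_to_m(ds$beta), co$sheet)
  dmps <- call_dmps(fit, ds$beta, co$sheet, fdr = 0.05)
  expect_s3_class(dmps, "dmp_table")
  expect_false(anyDuplicated(dmps$probe_id) > 0)
  expect_identical(dmps$direction, ifelse(dmps$delta_m < 0, "hypo", "hyper"))
  expect_equal(dmps$effect_size_pct,
               100 * (dmps$mean_beta_patients - dmps$mean_beta_controls))
  # q non-decreasing in p order
  expect_true(!is.unsorted(dmps$q_value[order(dmps$p_value)]))
  s <- summary(dmps)
  expect_identical(s$n_dmps, nrow(dmps))
  expect_equal(s$pct_hypo + s$pct_hyper, 100)
  # fdr = 0 gives a valid empty table
  empty <- call_dmps(fit, ds$beta, co$sheet, fdr = 0)
  expect_identical(nrow(empty), 0L)
  expect_identical(summary(empty)$n_dmps, 0L)
})

test_that("group coefficient sign matches group mean betas when balanced", {
  set.seed(99)
  n <- 40
  sheet <- toy_sheet(n, group = rep(c("patient", "control"), each = n / 2),
                     age = rep(round(rnorm(n / 2, 55, 8)), 2),
                     sex = rep(rep(c("male", "female"), length.out = n / 2), 2),
                     bmi = rep(round(rnorm(n / 2, 26, 3), 1), 2))
  beta <- matrix(runif(50 * n, 0.2, 0.8), 50, n,
                 dimnames = list(sprintf("cg%03d", 1:50), sheet$sample_id))
  beta[1:10, sheet$group == "patient"] <- beta[1:10, sheet$group == "patient"] + 0.1
  beta <- pmin(beta, 0.99)
  M <- beta_to_m(beta)
  fit <- fit_dmp_models(M, sheet)
  pat <- sheet$group == "patient"
  # with covariates exactly balanced across groups the group column is
  # orthogonal to them, so the adjusted coefficient equals the raw M-scale
  # group contrast
  dmean_m <- rowMeans(M[, pat]) - rowMeans(M[, !pat])
  expect_equal(fit$delta_m, unname(dmean_m), tolerance = 1e-10)
  # and for the planted (non-null) probes the beta-scale means agree in sign
  dmean_b <- rowMeans(beta[1:10, pat]) - rowMeans(beta[1:10, !pat])
  expect_true(all(sign(fit$delta_m[1:10]) == sign(dmean_b)))
})

test_that("moderated fit agrees with limma and plain OLS in direction", {
  co <- small_cohort(seed = 31)
  M <- beta_to_m(co$methylation$beta)
  plain <- fit_dmp_models(M, co$sheet)
  mod <- fit_dmp_models(M, co$sheet, moderate = TRUE)
  expect_equal(mod$delta_m, plain$delta_m, tolerance = 1e-10)
  expect_gt(cor(mod$t_stat, plain$t_stat), 0.98)
})
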