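# Synthetic-cohort generator. Emulates the statistical structure of an
# EPIC-style patient/control muscle methylation study: bimodal beta baselines,
# planted group shifts on the beta scale analysed later on the M scale,
# overlapping covariate distributions, methylation-coupled expression for a
# differentially expressed RNA subset, a strength phenotype driven by a
# co-regulated sub-module of those RNAs, and in-ICU exposure variables with
# planted directional methylation effects. Every draw descends from one
# master seed through per-stage child seeds.

#' Configure a synthetic cohort
#'
#' Returns a validated configuration for [simulate_cohort()]. Defaults encode
#' the emulated study conditions: 118 patients vs 30 controls, 63.6% of
#' planted differential positions hypomethylated, planted absolute beta
#' shifts averaging 0.026 with maximum 0.25, a ~2% differentially expressed
#' RNA fraction of which ~47% are strength-coupled, and a target
#' methylation-expression Spearman correlation of 0.5 for coupled pairs.
#' Probe and RNA counts default to 2000 each, a simulation scale at which
#' recovery statistics are estimable in seconds.
#'
#' @param n_patients,n_controls Sample sizes per group (`n_controls >= 3`).
#' @param n_probes,n_rnas Number of CpG probes (>= 10) and RNAs.
#' @param frac_true_dmps Fraction of probes given a planted group shift.
#' @param mean_abs_delta_beta,max_abs_delta_beta Target mean and maximum of
#'   the planted absolute beta-scale shifts; `mean <= max <= 0.5`.
#' @param frac_hypo Fraction of planted shifts that are negative
#'   (hypomethylated in patients).
#' @param frac_dernas Fraction of RNAs flagged as differentially expressed.
#' @param frac_strength_coupled Fraction of DERNAs coupled to the strength
#'   phenotype.
#' @param coupling_rho Target absolute Spearman correlation between a coupled
#'   probe's beta-values and its RNA's expression.
#' @param noise_sd_m Standard deviation of per-cell Gaussian noise on the
#'   M-value scale.
#' @param de_lfc Log2 expression shift (patients - controls) planted in
#'   DERNAs.
#' @param expr_noise_sd Residual log2-scale expression noise standard
#'   deviation per RNA.
#' @param exposures List of exposure definitions, each a list with `name`,
#'   `kind` ("binary" or "duration"), `effect` (beta-units per unit) and
#'   `prevalence` (binary kinds) or `mean_days` (duration kinds).
#' @param covariate_effects Named numeric vector of confounding effect sizes
#'   (beta-units per unit of centred age/sex/BMI), applied probe-wise with
#'   random sign.
#' @param frac_exposure_probes Fraction of planted DMPs each exposure acts on.
#' @param frac_failed_cells Fraction of detection-p cells failed at random.
#' @param frac_failed_probes Fraction of probes failed in most samples (these
#'   should be removed by the detection filter).
#' @param frac_intergenic Fraction of probes without gene links.
#' @param n_genes Number of genes in the simulated annotation.
#' @param seed Master seed; identical configurations with identical seeds
#'   produce identical cohorts.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 118L, n_controls = 30L,
                          n_probes = 2000L, n_rnas = 2000L,
                          frac_true_dmps = 0.05,
                          mean_abs_delta_beta = 0.026,
                          max_abs_delta_beta = 0.25,
                          frac_hypo = 0.636,
                          frac_dernas = 0.021,
                          frac_strength_coupled = 0.466,
                          coupling_rho = 0.5,
                          noise_sd_m = 0.5,
                          de_lfc = 1.0,
                          expr_noise_sd = 0.5,
                          exposures = default_exposures(),
                          covariate_effects = c(age = 0.0008, sex = 0.015, bmi = 0.0012),
                          frac_exposure_probes = 0.3,
                          frac_failed_cells = 0.002,
                          frac_failed_probes = 0.01,
                          frac_intergenic = 0.77,
                          n_genes = NULL,
                          seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
              n_probes = as.integer(n_probes), n_rnas = as.integer(n_rnas),
              frac_true_dmps = frac_true_dmps,
              mean_abs_delta_beta = mean_abs_delta_beta,
              max_abs_delta_beta = max_abs_delta_beta,
              frac_hypo = frac_hypo, frac_dernas = frac_dernas,
              frac_strength_coupled = frac_strength_coupled,
              coupling_rho = coupling_rho, noise_sd_m = noise_sd_m,
              de_lfc = de_lfc, expr_noise_sd = expr_noise_sd,
              exposures = exposures,
              covariate_effects = covariate_effects,
              frac_exposure_probes = frac_exposure_probes,
              frac_failed_cells = frac_failed_cells,
              frac_failed_probes = frac_failed_probes,
              frac_intergenic = frac_intergenic,
              n_genes = if (is.null(n_genes)) max(50L, round(n_probes / 3)) else as.integer(n_genes),
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

#' Default exposure definitions for the synthetic cohort
#'
#' Two binary in-ICU treatments and one duration exposure with planted
#' harmful methylation effects (pushing planted positions further from the
#' control mean).
#' @return List of exposure definition lists.
#' @export
default_exposures <- function() {
  list(
    list(name = "glucocorticoids", kind = "binary", effect = 0.05, prevalence = 0.29),
    list(name = "early_pn", kind = "binary", effect = 0.04, prevalence = 0.52),
    list(name = "benzodiazepine_days", kind = "duration", effect = 0.008, mean_days = 5)
  )
}

validate_cohort_config <- function(cfg) {
  for (f in c("frac_true_dmps", "frac_hypo", "frac_dernas", "frac_strength_coupled",
              "coupling_rho", "frac_exposure_probes", "frac_failed_cells",
              "frac_failed_probes", "frac_intergenic"))
    check_proportion(cfg[[f]], f)
  if (cfg$n_controls < 3) stop_field("n_controls", "must be at least 3")
  if (cfg$n_probes < 10) stop_field("n_probes", "must be at least 10")
  if (cfg$n_patients < 2) stop_field("n_patients", "must be at least 2")
  if (cfg$mean_abs_delta_beta > cfg$max_abs_delta_beta)
    stop_field("mean_abs_delta_beta", "must not exceed max_abs_delta_beta")
  if (cfg$max_abs_delta_beta > 0.5)
    stop_field("max_abs_delta_beta", "must not exceed 0.5")
  if (cfg$noise_sd_m <= 0) stop_field("noise_sd_m", "must be positive")
  if (cfg$expr_noise_sd <= 0) stop_field("expr_noise_sd", "must be positive")
  for (e in cfg$exposures) {
    if (!all(c("name", "kind", "effect") %in% names(e)))
      stop_field("exposures", "each exposure needs name, kind and effect")
    if (!e$kind %in% c("binary", "duration"))
      stop_field("exposures", paste0("unknown kind '", e$kind, "' for ", e$name))
  }
  invisible(cfg)
}

#' Simulate per-probe manifest-style annotation
#'
#' Non-intergenic probes receive 1-3 gene links, each with a gene-region
#' group drawn from TSS200/TSS1500/5UTR/Body/3UTR; about 2% of probes are
#' flagged as SNP-overlapping; intergenic probes carry no links. Probe design
#' type (I/II) provides the normalisation stratum.
#'
#' @param n_probes,n_genes Counts (positive).
#' @param frac_intergenic Fraction of probes with zero gene links.
#' @param seed Integer seed.
#' @param probe_ids Optional probe identifiers (generated if `NULL`).
#' @return A `probe_annotation` data frame.
#' @export
simulate_probe_annotation <- function(n_probes, n_genes, frac_intergenic = 0.77,
                                      seed = 1L, probe_ids = NULL) {
  if (n_probes < 1 || n_genes < 1) stop("counts must be positive", call. = FALSE)
  check_proportion(frac_intergenic, "frac_intergenic")
  with_seed(seed, {
    if (is.null(probe_ids)) probe_ids <- sprintf("cg%07d", seq_len(n_probes))
    genes <- sprintf("GENE%04d", seq_len(n_genes))
    intergenic <- stats::runif(n_probes) < frac_intergenic
    links <- vector("list", n_probes)
    empty <- data.frame(gene_id = character(0), region_group = character(0),
                        stringsAsFactors = FALSE)
    region_w <- c(TSS200 = 0.20, TSS1500 = 0.20, `5UTR` = 0.15, Body = 0.30, `3UTR` = 0.15)
    for (i in seq_len(n_probes)) {
      if (intergenic[i]) { links[[i]] <- empty; next }
      k <- sample.int(3L, 1L, prob = c(0.7, 0.2, 0.1))
      links[[i]] <- data.frame(
        gene_id = sample(genes, k),
        region_group = sample(names(region_w), k, replace = TRUE, prob = region_w),
        stringsAsFactors = FALSE)
    }
    ann <- data.frame(
      probe_id = probe_ids,
      chromosome = sample(c(1:22, "X"), n_probes, replace = TRUE),
      position = sample.int(1e8L, n_probes, replace = TRUE),
      snp_flag = stats::runif(n_probes) < 0.02,
      probe_type = sample(c("I", "II"), n_probes, replace = TRUE, prob = c(0.2, 0.8)),
      stringsAsFactors = FALSE)
    ann$links <- links
    class(ann) <- c("probe_annotation", "data.frame")
    ann
  })
}

# Planted |delta-beta| magnitudes: draw Exp(1), then map through
# m = max_target * (u / max(u))^gamma with gamma solved so the sample mean
# equals mean_target exactly. This pins both the mean and the maximum of the
# planted effects for every draw, not only in expectation.
draw_effect_magnitudes <- function(n, mean_target, max_target) {
  if (n == 0L) return(numeric(0))
  u <- stats::rexp(n)
  if (n == 1L) return(mean_target)
  base <- u / max(u)
  f <- function(g) mean(max_target * base^g) - mean_target
  if (f(1e-3) < 0) return(rep(mean_target, n))  # degenerate: targets too close
  if (f(500) > 0) {
    # too few values to reach the target mean while one sits at the maximum;
    # hold the maximum and spread the rest evenly (or forgo the maximum when
    # even that is out of reach)
    rest <- (n * mean_target - max_target) / (n - 1)
    if (rest < 0) return(rep(mean_target, n))
    return(c(max_target, rep(rest, n - 1)))
  }
  g <- stats::uniroot(f, c(1e-3, 500))$root
  max_target * base^g
}

#' Generate a seeded synthetic cohort with ground truth
#'
#' Produces a methylation dataset (beta + detection p), a sample sheet, an
#' expression dataset with RNA labels, a probe annotation, and the planted
#' ground truth used by recovery tests. Beta baselines are drawn from a
#' bimodal mixture (modes near 0.1 and 0.9 with an intermediate minority);
#' group shifts are planted on the beta scale in patients and clipped into
#' (0, 1); per-cell noise is Gaussian on the M scale; coupled RNA expression
#' is a monotone function of the linked probe's realised beta plus noise
#' calibrated so the expected Spearman correlation approximates
#' `coupling_rho`; the strength phenotype is a weighted sum of
#' strength-coupled DERNA expression plus noise.
#'
#' @param config A [cohort_config()].
#' @return List with elements `methylation` ([methylation_dataset()]),
#'   `sheet` (sample sheet data frame), `expression` (list `expr`, `labels`),
#'   `annotation` (`probe_annotation`), and `truth` (list `true_dmps`,
#'   `true_derna_ids`, `coupling_map`, `strength_coupled_rna_ids`,
#'   `exposure_effect_map`).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  validate_cohort_config(config)
  cfg <- config
  seeds <- child_seeds(cfg$seed, c("annotation", "covariates", "effects",
                                   "methylation", "expression", "strength",
                                   "detection"))
  n <- cfg$n_patients + cfg$n_controls
  sample_ids <- c(sprintf("P%03d", seq_len(cfg$n_patients)),
                  sprintf("C%03d", seq_len(cfg$n_controls)))
  group <- rep(c("patient", "control"), c(cfg$n_patients, cfg$n_controls))
  g <- as.numeric(group == "patient")

  ann <- simulate_probe_annotation(cfg$n_probes, cfg$n_genes, cfg$frac_intergenic,
                                   seed = seeds[["annotation"]])
  probe_ids <- ann$probe_id

  ## sample sheet: overlapping patient/control covariate distributions
  sheet <- with_seed(seeds[["covariates"]], {
    age <- ifelse(g == 1, stats::rnorm(n, 58, 11), stats::rnorm(n, 61, 6))
    age <- pmin(pmax(round(age), 20), 90)
    sex <- ifelse(stats::runif(n) < 0.79, "male", "female")
    bmi <- ifelse(g == 1, stats::rnorm(n, 27.3, 4.5), stats::rnorm(n, 26.4, 3.3))
    bmi <- round(pmin(pmax(bmi, 16), 45), 1)
    sh <- data.frame(sample_id = sample_ids, group = group, age = age,
                     sex = sex, bmi = bmi, stringsAsFactors = FALSE)
    for (e in cfg$exposures) {
      v <- rep(NA_real_, n)
      if (e$kind == "binary") {
        v[g == 1] <- as.numeric(stats::runif(cfg$n_patients) < (e$prevalence %||% 0.3))
      } else {
        v[g == 1] <- round(stats::rexp(cfg$n_patients, 1 / (e$mean_days %||% 5)))
      }
      sh[[e$name]] <- v
    }
    sh
  })

  ## planted effects and exposure truth
  eff <- with_seed(seeds[["effects"]], {
    n_true <- round(cfg$frac_true_dmps * cfg$n_probes)
    true_idx <- sort(sample.int(cfg$n_probes, n_true))
    mags <- draw_effect_magnitudes(n_true, cfg$mean_abs_delta_beta, cfg$max_abs_delta_beta)
    signs <- ifelse(stats::runif(n_true) < cfg$frac_hypo, -1, 1)
    exposure_map <- list()
    for (e in cfg$exposures) {
      k <- round(cfg$frac_exposure_probes * n_true)
      if (k > 0) {
        pick <- sample(seq_len(n_true), k)
        exposure_map[[e$name]] <- data.frame(
          exposure = e$name, probe_id = probe_ids[true_idx[pick]],
          effect = e$effect * signs[pick],   # aligned with planted sign: harmful
          stringsAsFactors = FALSE)
      }
    }
    list(true_idx = true_idx, delta = signs * mags,
         exposure_map = do.call(rbind, exposure_map))
  })

  ## methylation matrix
  meth <- with_seed(seeds[["methylation"]], {
    mode <- sample.int(3L, cfg$n_probes, replace = TRUE, prob = c(0.4, 0.4, 0.2))
    mu <- numeric(cfg$n_probes)
    mu[mode == 1] <- stats::rbeta(sum(mode == 1), 4, 36)    # low-methylation mode
    mu[mode == 2] <- stats::rbeta(sum(mode == 2), 36, 4)    # high-methylation mode
    mu[mode == 3] <- stats::rbeta(sum(mode == 3), 8, 8)     # intermediate minority
    base <- matrix(mu, cfg$n_probes, n)
    delta_full <- numeric(cfg$n_probes)
    delta_full[eff$true_idx] <- eff$delta
    base <- base + outer(delta_full, g)
    covs <- cbind(age = sheet$age - mean(sheet$age),
                  sex = as.numeric(sheet$sex == "male") - mean(sheet$sex == "male"),
                  bmi = sheet$bmi - mean(sheet$bmi))
    for (cv in names(cfg$covariate_effects)) {
      w <- cfg$covariate_effects[[cv]] * sample(c(-1, 1), cfg$n_probes, replace = TRUE)
      base <- base + outer(w, covs[, cv])
    }
    if (!is.null(eff$exposure_map)) {
      for (i in seq_len(nrow(eff$exposure_map))) {
        row <- eff$exposure_map[i, ]
        x <- sheet[[row$exposure]]; x[is.na(x)] <- 0
        pi_ <- match(row$probe_id, probe_ids)
        base[pi_, ] <- base[pi_, ] + row$effect * x
      }
    }
    base <- pmin(pmax(base, 0.005), 0.995)
    M <- beta_to_m(base) + matrix(stats::rnorm(cfg$n_probes * n, sd = cfg$noise_sd_m),
                                  cfg$n_probes, n)
    beta <- m_to_beta(M)
    dimnames(beta) <- list(probe_ids, sample_ids)
    beta
  })

  ## expression with DMP coupling
  expr_out <- with_seed(seeds[["expression"]], {
    rna_ids <- sprintf("RNA%05d", seq_len(cfg$n_rnas))
    n_derna <- round(cfg$frac_dernas * cfg$n_rnas)
    derna_idx <- if (n_derna > 0) sort(sample.int(cfg$n_rnas, n_derna)) else integer(0)
    n_strength <- round(cfg$frac_strength_coupled * n_derna)
    strength_idx <- if (n_strength > 0) sort(sample(derna_idx, n_strength)) else integer(0)
    baseline <- stats::rnorm(cfg$n_rnas, 8, 1.5)
    expr <- matrix(stats::rnorm(cfg$n_rnas * n, sd = cfg$expr_noise_sd),
                   cfg$n_rnas, n, dimnames = list(rna_ids, sample_ids))
    expr <- baseline + expr
    gc <- g - mean(g)
    var_g <- mean(gc^2)
    Fz <- stats::rnorm(n)  # latent co-expression factor of the strength module
    coupling <- NULL
    if (n_derna > 0) {
      can_couple <- cfg$coupling_rho > 0 && length(eff$true_idx) > 0
      coupled_probe <- if (can_couple)
        sample(eff$true_idx, n_derna, replace = n_derna > length(eff$true_idx))
      else rep(NA_integer_, n_derna)
      sign_r <- sample(c(-1, 1), n_derna, replace = TRUE)
      r_p <- 2 * sin(pi * cfg$coupling_rho / 6)  # Pearson target for the Spearman aim
      v <- cfg$expr_noise_sd^2                   # non-group variance budget
      L <- cfg$de_lfc
      for (j in seq_len(n_derna)) {
        r <- derna_idx[j]
        lam <- if (r %in% strength_idx) 0.8 else 0
        if (can_couple) {
          # expr = baseline + sign_r * (a * z + de_lfc * gc) + tau * eps, with
          # z the standardised beta of the linked probe; a solves
          # corr(expr, z) = sign_r * r_p given the empirical cov(gc, z),
          # keeping the group shift at exactly +/- de_lfc and the non-group
          # variance at the v budget.
          z <- as.numeric(scale(meth[coupled_probe[j], ]))
          cz <- mean(gc * z)
          disc <- (L * cz)^2 * ((1 - r_p^2)^2 - 1) + r_p^2 * (v + L^2 * var_g)
          a <- if (disc > 0) -L * cz * (1 - r_p^2) + sqrt(disc) else r_p * sqrt(v)
          a <- min(max(a, 0), sqrt(v) * 0.99)
          tau <- sqrt(v - a^2)
          noise <- tau * (lam * Fz + sqrt(1 - lam^2) * stats::rnorm(n))
          expr[r, ] <- baseline[r] + sign_r[j] * (a * z + L * gc) + noise
        } else {
          noise <- cfg$expr_noise_sd * (lam * Fz + sqrt(1 - lam^2) * stats::rnorm(n))
          expr[r, ] <- baseline[r] + sign_r[j] * L * gc + noise
        }
      }
      coupling <- if (can_couple)
        data.frame(probe_id = probe_ids[coupled_probe], rna_id = rna_ids[derna_idx],
                   rho = sign_r * cfg$coupling_rho, stringsAsFactors = FALSE)
      else NULL
    }
    pathway <- rep("none", cfg$n_rnas)
    if (n_derna > 0)
      pathway[derna_idx] <- sample(c("mitochondrial", "lipid", "fibrosis", "none"),
                                   n_derna, replace = TRUE,
                                   prob = c(0.30, 0.25, 0.15, 0.30))
    labels <- data.frame(rna_id = rna_ids,
                         derna = seq_len(cfg$n_rnas) %in% derna_idx,
                         strength_associated = seq_len(cfg$n_rnas) %in% strength_idx,
                         pathway = pathway, stringsAsFactors = FALSE)
    list(expr = expr, labels = labels, derna_idx = derna_idx,
         strength_idx = strength_idx, Fz = Fz, coupling = coupling)
  })

  ## strength phenotype: weighted sum of strength-coupled DERNA expression
  sheet$strength <- with_seed(seeds[["strength"]], {
    s <- 100 - 8 * g + 3 * stats::rnorm(n)
    if (length(expr_out$strength_idx)) {
      sub <- expr_out$expr[expr_out$strength_idx, , drop = FALSE]
      zsub <- t(scale(t(sub)))
      # orient each RNA by its factor loading so contributions add coherently
      w <- sign(as.numeric(zsub %*% expr_out$Fz))
      msum <- colMeans(w * zsub)
      s <- s - 10 * msum
    }
    round(s, 1)
  })

  ## detection p-values
  detp <- with_seed(seeds[["detection"]], {
    dp <- matrix(stats::runif(cfg$n_probes * n, 0, 0.005), cfg$n_probes, n,
                 dimnames = list(probe_ids, sample_ids))
    fail <- stats::runif(length(dp)) < cfg$frac_failed_cells
    dp[fail] <- stats::runif(sum(fail), 0.02, 1)
    n_bad <- round(cfg$frac_failed_probes * cfg$n_probes)
    if (n_bad > 0) {
      bad <- sample.int(cfg$n_probes, n_bad)
      for (b in bad) {
        cols <- sample.int(n, ceiling(0.6 * n))
        dp[b, cols] <- stats::runif(length(cols), 0.02, 1)
      }
    }
    dp
  })

  truth <- list(
    true_dmps = data.frame(probe_id = probe_ids[eff$true_idx],
                           delta_beta = eff$delta, stringsAsFactors = FALSE),
    true_derna_ids = expr_out$labels$rna_id[expr_out$labels$derna],
    coupling_map = expr_out$coupling,
    strength_coupled_rna_ids = expr_out$labels$rna_id[expr_out$labels$strength_associated],
    exposure_effect_map = eff$exposure_map)

  list(methylation = methylation_dataset(meth, detp),
       sheet = sheet,
       expression = list(expr = expr_out$expr, labels = expr_out$labels),
       annotation = ann,
       truth = truth,
       config = cfg)
}

#' Write a simulated cohort to a directory of plain-text files
#'
#' Emits the beta and detection-p matrices (TSV), sample sheet (CSV), probe
#' annotation (TSV), expression matrix and RNA labels (TSV), ground-truth
#' tables (TSV) and the configuration (YAML).
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_methylation_dataset(cohort$methylation, p("beta.tsv"), p("detection_p.tsv"))
  write_sample_sheet(cohort$sheet, p("sample_sheet.csv"))
  write_probe_annotation(cohort$annotation, p("annotation.tsv"))
  write_id_matrix(cohort$expression$expr, p("expression.tsv"), "rna_id")
  utils::write.table(cohort$expression$labels, p("rna_labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth$true_dmps, p("truth_dmps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$truth$coupling_map))
    utils::write.table(cohort$truth$coupling_map, p("truth_coupling.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$truth$exposure_effect_map))
    utils::write.table(cohort$truth$exposure_effect_map, p("truth_exposures.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- cohort$config
  cfg$covariate_effects <- as.list(cfg$covariate_effects)
  yaml::write_yaml(unclass(cfg), p("config.yaml"))
  invisible(dir)
}
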