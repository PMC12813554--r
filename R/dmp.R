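# Per-probe covariate-adjusted differential methylation on M-values.

dmp_design <- function(sheet) {
  validate_sample_sheet(sheet)
  X <- cbind(intercept = 1,
             group = as.numeric(sheet$group == "patient"),
             age = sheet$age,
             sex = as.numeric(sheet$sex == "male"),
             bmi = sheet$bmi)
  if (sum(X[, "group"] == 1) < 2 || sum(X[, "group"] == 0) < 2)
    stop("need at least 2 samples per group", call. = FALSE)
  X
}

#' Fit per-probe linear models on M-values
#'
#' For every probe, ordinary least squares of the M-value on
#' \[intercept, group, age, sex, BMI\], with a two-sided t-test on the group
#' coefficient (patients minus controls) at `n - 5` residual degrees of
#' freedom. With `moderate = TRUE`, empirical-Bayes variance moderation
#' (limma) replaces the plain OLS t-test.
#'
#' @param M Numeric matrix of M-values, probes x samples.
#' @param sheet Sample sheet data frame matching the columns of `M`.
#' @param moderate Use limma empirical-Bayes moderated t-statistics
#'   (default `FALSE`, plain OLS).
#' @return A `dmp_fit` data frame with columns `probe_id`, `delta_m`,
#'   `t_stat`, `p_value`, `df`.
#' @export
fit_dmp_models <- function(M, sheet, moderate = FALSE) {
  stopifnot(is.matrix(M))
  if (!identical(colnames(M), sheet$sample_id))
    sheet <- sheet[match(colnames(M), sheet$sample_id), , drop = FALSE]
  if (anyNA(sheet$sample_id))
    stop("samples in matrix and sheet do not match", call. = FALSE)
  X <- dmp_design(sheet)
  if (moderate) {
    fit <- limma::eBayes(limma::lmFit(M, X))
    res <- data.frame(probe_id = rownames(M),
                      delta_m = fit$coefficients[, "group"],
                      t_stat = fit$t[, "group"],
                      p_value = fit$p.value[, "group"],
                      df = fit$df.total,
                      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    f <- ols_fit_matrix(t(M), X)
    res <- data.frame(probe_id = rownames(M),
                      delta_m = f$coef["group", ],
                      t_stat = f$t["group", ],
                      p_value = f$p["group", ],
                      df = f$df,
                      stringsAsFactors = FALSE, row.names = NULL)
  }
  class(res) <- c("dmp_fit", "data.frame")
  res
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values: `q_i = min_{j: p_(j) >= p_(i)} m p_(j) / j`,
#' capped at 1, returned in input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) stop("p-values must be numeric", call. = FALSE)
  if (length(p_values) && (min(p_values, na.rm = TRUE) < 0 || max(p_values, na.rm = TRUE) > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Call differentially methylated positions
#'
#' Applies the FDR threshold to a [fit_dmp_models()] result and attaches the
#' beta-scale effect size (100 x difference of unadjusted group mean betas)
#' and the direction (hypo if the adjusted group coefficient on the M scale
#' is negative, hyper otherwise).
#'
#' @param fit A `dmp_fit` data frame.
#' @param beta Beta-value matrix covering the fitted probes.
#' @param sheet Sample sheet matching the columns of `beta`.
#' @param fdr FDR threshold, default 0.05.
#' @return A `dmp_table` data frame (possibly empty) with columns `probe_id`,
#'   `delta_m`, `t_stat`, `p_value`, `q_value`, `mean_beta_patients`,
#'   `mean_beta_controls`, `effect_size_pct`, `direction`, plus a `summary`
#'   attribute (count, percent hypo/hyper, mean and max absolute effect size).
#' @export
call_dmps <- function(fit, beta, sheet, fdr = 0.05) {
  stopifnot(inherits(fit, "data.frame"), is.matrix(beta))
  if (!all(fit$probe_id %in% rownames(beta)))
    stop("fit and beta matrix must share the probe set", call. = FALSE)
  sheet <- sheet[match(colnames(beta), sheet$sample_id), , drop = FALSE]
  q <- bh_adjust(fit$p_value)
  keep <- which(q < fdr)
  pat <- sheet$group == "patient"
  bsub <- beta[fit$probe_id[keep], , drop = FALSE]
  mbp <- if (length(keep)) rowMeans(bsub[, pat, drop = FALSE]) else numeric(0)
  mbc <- if (length(keep)) rowMeans(bsub[, !pat, drop = FALSE]) else numeric(0)
  tab <- data.frame(probe_id = fit$probe_id[keep],
                    delta_m = fit$delta_m[keep],
                    t_stat = fit$t_stat[keep],
                    p_value = fit$p_value[keep],
                    q_value = q[keep],
                    mean_beta_patients = mbp,
                    mean_beta_controls = mbc,
                    effect_size_pct = 100 * (mbp - mbc),
                    direction = ifelse(fit$delta_m[keep] < 0, "hypo", "hyper"),
                    stringsAsFactors = FALSE, row.names = NULL)
  tab <- tab[order(tab$p_value), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "summary") <- dmp_summary_stats(tab)
  class(tab) <- c("dmp_table", "data.frame")
  tab
}

dmp_summary_stats <- function(tab) {
  n <- nrow(tab)
  list(n_dmps = n,
       n_hypo = sum(tab$direction == "hypo"),
       n_hyper = sum(tab$direction == "hyper"),
       pct_hypo = if (n) 100 * sum(tab$direction == "hypo") / n else NA_real_,
       pct_hyper = if (n) 100 * sum(tab$direction == "hyper") / n else NA_real_,
       mean_abs_effect_pct = if (n) mean(abs(tab$effect_size_pct)) else NA_real_,
       max_abs_effect_pct = if (n) max(abs(tab$effect_size_pct)) else NA_real_)
}

#' @export
print.dmp_table <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("dmp_table: %d DMPs (%.1f%% hypo, %.1f%% hyper)\n",
              s$n_dmps, s$pct_hypo %||% NA, s$pct_hyper %||% NA))
  if (s$n_dmps)
    cat(sprintf("  |effect size|: mean %.2f%%, max %.2f%%\n",
                s$mean_abs_effect_pct, s$max_abs_effect_pct))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' @export
summary.dmp_table <- function(object, ...) attr(object, "summary")

#' Write a DMP table and its summary
#'
#' @param tab A `dmp_table`.
#' @param path TSV output path for the table.
#' @param summary_path Optional JSON output path for the summary counts.
#' @return Invisibly, `path`.
#' @export
write_dmp_table <- function(tab, path, summary_path = NULL) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(summary_path))
    jsonlite::write_json(attr(tab, "summary"), summary_path,
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}
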