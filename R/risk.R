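# Risk-factor association: one joint multivariable linear model per DMP with
# the beta-value as dependent variable and all candidate factors as
# covariates (mutual adjustment), fitted in patients only, with the
# harmful/protective direction classification.

#' Fit per-DMP risk-factor models
#'
#' For each DMP, ordinary least squares of the beta-value (not the M-value;
#' effect sizes are then in methylation-proportion units) on all supplied
#' factors jointly, in patients only. Per-factor two-sided t-tests;
#' significance at raw `p < p_threshold` (no multiple-testing adjustment,
#' matching the exploratory single-association convention). Constant factors
#' are dropped with a warning; remaining rank deficiency is an error naming
#' the collinear columns. Significant associations are classified
#' harmful/protective via [classify_direction()].
#'
#' @param beta_dmps Beta matrix restricted to DMPs, probes x samples.
#' @param sheet Sample sheet with the factor columns; only rows with
#'   `group == "patient"` are used.
#' @param factors Character vector of factor column names in `sheet`.
#' @param dmp_direction Named character vector (`hypo`/`hyper`) per DMP, or a
#'   `dmp_table` from [call_dmps()].
#' @param p_threshold Significance threshold, default 0.05.
#' @return A `risk_result` data frame with one row per DMP x factor:
#'   `probe_id`, `factor`, `coefficient`, `p_value`, `significant`,
#'   `dmp_direction`, `classification` (`NA` unless significant; zero
#'   coefficients are excluded from classification and tallied in the
#'   `n_zero_coefficients` attribute).
#' @export
fit_risk_models <- function(beta_dmps, sheet, factors, dmp_direction,
                            p_threshold = 0.05) {
  stopifnot(is.matrix(beta_dmps))
  if (inherits(dmp_direction, "data.frame"))
    dmp_direction <- stats::setNames(dmp_direction$direction, dmp_direction$probe_id)
  miss <- setdiff(factors, names(sheet))
  if (length(miss))
    stop("factors absent from sample sheet: ", paste(miss, collapse = ", "),
         call. = FALSE)
  sheet <- sheet[match(colnames(beta_dmps), sheet$sample_id), , drop = FALSE]
  pat <- sheet$group == "patient"
  Y <- t(beta_dmps[, pat, drop = FALSE])
  cols <- list(intercept = rep(1, sum(pat)))
  for (f in factors) {
    v <- sheet[[f]][pat]
    if (is.character(v) || is.factor(v)) {
      # dummy-code against the first observed level as reference
      v <- factor(v)
      mm <- stats::model.matrix(~v)[, -1, drop = FALSE]
      colnames(mm) <- paste0(f, "_", levels(v)[-1])
      for (cn in colnames(mm)) cols[[cn]] <- mm[, cn]
    } else {
      if (anyNA(v))
        stop("factor '", f, "' has missing values among patients", call. = FALSE)
      cols[[f]] <- v
    }
  }
  X <- do.call(cbind, cols)
  constant <- apply(X[, -1, drop = FALSE], 2, function(x) length(unique(x)) == 1)
  if (any(constant)) {
    warning("dropping constant factor column(s): ",
            paste(names(constant)[constant], collapse = ", "), call. = FALSE)
    X <- X[, c(TRUE, !constant), drop = FALSE]
  }
  f <- ols_fit_matrix(Y, X, drop_aliased = TRUE)
  fac_names <- setdiff(rownames(f$coef), "intercept")
  probe_ids <- rownames(beta_dmps)
  out <- do.call(rbind, lapply(fac_names, function(fc) {
    data.frame(probe_id = probe_ids, factor = fc,
               coefficient = f$coef[fc, ], p_value = f$p[fc, ],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out$significant <- out$p_value < p_threshold
  out$dmp_direction <- unname(dmp_direction[out$probe_id])
  if (anyNA(out$dmp_direction))
    stop("every DMP needs a direction label", call. = FALSE)
  cls <- rep(NA_character_, nrow(out))
  sig <- which(out$significant)
  n_zero <- 0L
  for (i in sig) {
    if (out$coefficient[i] == 0) { n_zero <- n_zero + 1L; next }
    cls[i] <- classify_direction(out$coefficient[i], out$dmp_direction[i])
  }
  out$classification <- cls
  attr(out, "n_zero_coefficients") <- n_zero
  class(out) <- c("risk_result", "data.frame")
  out
}

#' Classify a risk-factor association as harmful or protective
#'
#' A negative association with a hypomethylated DMP, or a positive
#' association with a hypermethylated DMP, means higher exposure pushes
#' methylation further from the control level: harmful. The opposite signs
#' pull methylation back toward the control level: protective. Antisymmetric
#' in the coefficient sign.
#'
#' @param coefficient Nonzero regression coefficient of the factor.
#' @param dmp_direction `"hypo"` or `"hyper"`.
#' @return `"harmful"` or `"protective"`.
#' @export
classify_direction <- function(coefficient, dmp_direction) {
  stopifnot(dmp_direction %in% c("hypo", "hyper"))
  if (coefficient == 0)
    stop("zero coefficient has no direction", call. = FALSE)
  harmful <- (dmp_direction == "hypo" && coefficient < 0) ||
             (dmp_direction == "hyper" && coefficient > 0)
  if (harmful) "harmful" else "protective"
}

#' Summarise risk-factor associations per factor and direction stratum
#'
#' Counts significant classified associations per factor within the hypo- and
#' hyper-methylated DMP strata (plus a combined `all` stratum) and the
#' percentage classified harmful vs protective.
#'
#' @param results A `risk_result` from [fit_risk_models()].
#' @return Data frame with columns `factor`, `stratum`, `n_associations`,
#'   `pct_harmful`, `pct_protective`.
#' @export
summarize_factors <- function(results) {
  res <- results[!is.na(results$classification), , drop = FALSE]
  if (!nrow(res))
    return(data.frame(factor = character(0), stratum = character(0),
                      n_associations = integer(0), pct_harmful = numeric(0),
                      pct_protective = numeric(0), stringsAsFactors = FALSE))
  one <- function(d, fac, stratum) {
    n <- nrow(d)
    data.frame(factor = fac, stratum = stratum, n_associations = n,
               pct_harmful = 100 * sum(d$classification == "harmful") / n,
               pct_protective = 100 * sum(d$classification == "protective") / n,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (fac in unique(res$factor)) {
    sub <- res[res$factor == fac, , drop = FALSE]
    for (st in c("hypo", "hyper")) {
      d <- sub[sub$dmp_direction == st, , drop = FALSE]
      if (nrow(d)) rows[[length(rows) + 1L]] <- one(d, fac, st)
    }
    rows[[length(rows) + 1L]] <- one(sub, fac, "all")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
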