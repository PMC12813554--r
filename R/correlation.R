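# Methylation-expression correlation enrichment: Spearman correlation of
# every DMP's beta-values with every RNA, the |rho| > tau "biologically
# relevant" proportion per RNA group, pooled two-proportion Z comparisons,
# and ECDF / asymptotic two-sample Kolmogorov-Smirnov distribution tests.

#' Flag differentially expressed RNAs
#'
#' Per-RNA OLS of (log-scale, normalised) expression on
#' \[group, age, sex, BMI\] with BH adjustment across RNAs; an RNA is flagged
#' when its group-coefficient q-value passes the FDR threshold.
#'
#' @param expr Expression matrix, RNAs x samples.
#' @param sheet Sample sheet matching the columns of `expr`.
#' @param fdr FDR threshold, default 0.05.
#' @return Logical vector named by RNA id.
#' @export
label_dernas <- function(expr, sheet, fdr = 0.05) {
  stopifnot(is.matrix(expr))
  sheet <- sheet[match(colnames(expr), sheet$sample_id), , drop = FALSE]
  if (anyNA(sheet$sample_id))
    stop("samples in matrix and sheet do not match", call. = FALSE)
  X <- dmp_design(sheet)
  f <- ols_fit_matrix(t(expr), X)
  q <- bh_adjust(f$p["group", ])
  stats::setNames(q < fdr, rownames(expr))
}

#' Flag DERNAs associated with muscle strength
#'
#' Spearman correlation of each RNA's expression with the strength phenotype
#' among patients, BH-adjusted across all RNAs; flags are restricted to
#' DERNAs (a non-DERNA is never flagged).
#'
#' @param expr Expression matrix, RNAs x samples.
#' @param strength Numeric strength phenotype, one value per column of
#'   `expr` (controls may be `NA`).
#' @param derna Logical DERNA flags, one per RNA.
#' @param patients Logical vector marking patient samples.
#' @param fdr FDR threshold, default 0.05.
#' @return Logical vector named by RNA id.
#' @export
label_strength_association <- function(expr, strength, derna, patients, fdr = 0.05) {
  stopifnot(is.matrix(expr), length(strength) == ncol(expr),
            length(derna) == nrow(expr), length(patients) == ncol(expr))
  use <- patients & !is.na(strength)
  s <- strength[use]
  if (length(unique(s)) < 2)
    stop("strength phenotype is constant among patients", call. = FALSE)
  sub <- expr[, use, drop = FALSE]
  rho <- as.numeric(spearman_matrix(sub, matrix(s, nrow = 1)))
  n <- length(s)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  q <- bh_adjust(p)
  stats::setNames(q < fdr & derna, rownames(expr))
}

rank_standardize <- function(m) {
  # average-rank each row, then centre/scale to unit variance (constant -> NA)
  r <- t(apply(m, 1, rank, ties.method = "average"))
  if (nrow(m) == 1L) r <- matrix(r, nrow = 1)
  mu <- rowMeans(r)
  sd <- sqrt(rowSums((r - mu)^2))
  sd[sd == 0] <- NA_real_
  (r - mu) / sd
}

#' Spearman correlation matrix between DMP betas and RNA expression
#'
#' Pearson correlation of average-tie ranks, computed row-block by row-block
#' so memory stays bounded for large probe sets. Constant rows yield `NA`
#' correlations; the count of such rows is reported via a message and the
#' `n_constant_rows` attribute.
#'
#' @param dmp_betas Matrix, DMPs x samples.
#' @param expr Matrix, RNAs x samples, same ordered sample set.
#' @param chunk_size Number of DMP rows correlated per block.
#' @return Matrix of Spearman rho, DMPs x RNAs, attribute `n_constant_rows`.
#' @export
spearman_matrix <- function(dmp_betas, expr, chunk_size = 500L) {
  stopifnot(is.matrix(dmp_betas), is.matrix(expr),
            ncol(dmp_betas) == ncol(expr))
  if (!is.null(colnames(dmp_betas)) && !is.null(colnames(expr)) &&
      !identical(colnames(dmp_betas), colnames(expr)))
    stop("sample columns must match and be in the same order", call. = FALSE)
  if (ncol(expr) < 4) stop("need at least 4 shared samples", call. = FALSE)
  ze <- rank_standardize(expr)
  out <- matrix(NA_real_, nrow(dmp_betas), ncol = nrow(expr),
                dimnames = list(rownames(dmp_betas), rownames(expr)))
  n_const <- sum(is.na(ze[, 1]))
  for (start in seq(1, nrow(dmp_betas), by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, nrow(dmp_betas))
    zb <- rank_standardize(dmp_betas[idx, , drop = FALSE])
    n_const <- n_const + sum(is.na(zb[, 1]))
    out[idx, ] <- tcrossprod(zb, ze)
  }
  out <- pmin(pmax(out, -1), 1)
  if (n_const > 0)
    message(n_const, " constant row(s) produced undefined correlations (NA)")
  attr(out, "n_constant_rows") <- n_const
  out
}

#' Proportion of biologically relevant correlations in an RNA group
#'
#' Counts correlations with `|rho|` strictly greater than `tau` among the
#' columns of `rho` belonging to `group`. Missing correlations are excluded
#' from numerator and denominator.
#'
#' @param rho Spearman correlation matrix, DMPs x RNAs.
#' @param group RNA ids (column names) or logical/integer column selector.
#' @param tau Relevance threshold, default 0.3 (strict inequality).
#' @return List with `n_pairs`, `n_relevant`, `proportion`.
#' @export
proportion_relevant <- function(rho, group, tau = 0.3) {
  if (is.character(group)) group <- match(group, colnames(rho))
  sub <- rho[, group, drop = FALSE]
  if (!length(sub)) stop("empty RNA group", call. = FALSE)
  ok <- !is.na(sub)
  n_pairs <- sum(ok)
  if (n_pairs == 0) stop("empty RNA group", call. = FALSE)
  n_rel <- sum(abs(sub[ok]) > tau)
  list(n_pairs = n_pairs, n_relevant = n_rel, proportion = n_rel / n_pairs)
}

#' Pooled two-proportion Z-test
#'
#' \eqn{z = (\hat p_1 - \hat p_2) / \sqrt{\hat p (1-\hat p)(1/n_1 + 1/n_2)}}
#' with the pooled estimate \eqn{\hat p = (x_1+x_2)/(n_1+n_2)}, two-sided
#' normal p-value, no continuity correction. A degenerate pooled proportion
#' (0 or 1) returns `z = 0`, `p = 1`, flagged. P-values below
#' double-precision eps carry the conventional display string `"< 2.2e-16"`
#' alongside the raw number.
#'
#' @param x1,n1,x2,n2 Successes and totals of the two groups.
#' @return List with `z`, `p`, `p_display`, `degenerate`.
#' @export
two_proportion_ztest <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  pp <- (x1 + x2) / (n1 + n2)
  if (pp <= 0 || pp >= 1)
    return(list(z = 0, p = 1, p_display = "1", degenerate = TRUE))
  z <- (x1 / n1 - x2 / n2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  p <- 2 * stats::pnorm(-abs(z))
  list(z = z, p = p, p_display = format_pvalue(p), degenerate = FALSE)
}

#' Empirical cumulative distribution function
#'
#' Right-continuous step function rising from 0 to 1, returned as its sorted
#' unique support with cumulative proportions (the proportion of observations
#' less than or equal to each value).
#'
#' @param values Non-empty numeric vector.
#' @return Data frame with columns `value` and `cumprop`.
#' @export
ecdf_table <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values to form an ECDF from", call. = FALSE)
  F <- stats::ecdf(values)
  v <- sort(unique(values))
  data.frame(value = v, cumprop = F(v))
}

#' Asymptotic two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two ECDFs over the pooled support;
#' the p-value uses the asymptotic series
#' \eqn{Q(\lambda) = 2\sum_{k\ge1} (-1)^{k-1} e^{-2k^2\lambda^2}} at
#' \eqn{\lambda = (\sqrt{n_e} + 0.12 + 0.11/\sqrt{n_e}) D} with effective
#' size \eqn{n_e = n_a n_b / (n_a + n_b)}, capped into \[0, 1\].
#'
#' @param a,b Non-empty numeric vectors.
#' @return List with `D`, `p`, `n_effective`.
#' @export
ks_two_sample <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both samples must be non-empty", call. = FALSE)
  support <- sort(unique(c(a, b)))
  Fa <- stats::ecdf(a)(support)
  Fb <- stats::ecdf(b)(support)
  D <- max(abs(Fa - Fb))
  ne <- length(a) * length(b) / (length(a) + length(b))
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  list(D = D, p = ks_q(lambda), n_effective = ne)
}

# Asymptotic KS tail Q(lambda) = 2 sum_{k>=1} (-1)^(k-1) exp(-2 k^2 lambda^2),
# summed until the terms vanish (the series needs ~1/lambda terms to settle
# when lambda is small; Q -> 1 as lambda -> 0).
ks_q <- function(lambda) {
  if (lambda <= 0) return(1)
  s <- 0; k <- 1
  repeat {
    term <- (-1)^(k - 1) * exp(-2 * k^2 * lambda^2)
    s <- s + term
    if (abs(term) < 1e-12 || k > 1e6) break
    k <- k + 1
  }
  min(max(2 * s, 0), 1)
}

#' Compare correlation strength across RNA groups
#'
#' Runs the full comparison grid: DERNA vs non-DERNA; strength-associated vs
#' non-strength DERNAs; and, per pathway (mitochondrial, lipid, fibrosis),
#' strength vs non-strength DERNAs. For each comparison it reports the
#' |rho| > tau proportions, the pooled two-proportion Z-test and the
#' asymptotic two-sample KS test on the full rho distributions. Comparisons
#' with an empty side are skipped with a message.
#'
#' @param rho Spearman correlation matrix, DMPs x RNAs (columns named).
#' @param labels RNA label data frame with `rna_id`, `derna`,
#'   `strength_associated`, `pathway`.
#' @param tau Relevance threshold, default 0.3.
#' @return A `corr_enrichment` object: list with `groups` (per-group counts
#'   and proportions) and `comparisons` (per-pair z/KS statistics), plus
#'   `tau`.
#' @export
compare_rna_groups <- function(rho, labels, tau = 0.3) {
  validate_rna_labels(labels)
  labels <- labels[match(colnames(rho), labels$rna_id), , drop = FALSE]
  if (anyNA(labels$rna_id))
    stop("every rho column needs an RNA label row", call. = FALSE)
  grp <- list(
    derna = labels$derna,
    non_derna = !labels$derna,
    strength = labels$derna & labels$strength_associated,
    non_strength = labels$derna & !labels$strength_associated)
  for (pw in c("mitochondrial", "lipid", "fibrosis")) {
    grp[[paste0(pw, "_strength")]] <- labels$pathway == pw & labels$strength_associated
    grp[[paste0(pw, "_non_strength")]] <- labels$pathway == pw & !labels$strength_associated
  }
  groups <- do.call(rbind, lapply(names(grp), function(g) {
    sel <- grp[[g]]
    if (!any(sel))
      return(data.frame(group = g, n_rnas = 0L, n_pairs = 0L,
                        n_relevant = 0L, proportion = NA_real_,
                        stringsAsFactors = FALSE))
    pr <- proportion_relevant(rho, sel, tau)
    data.frame(group = g, n_rnas = sum(sel), n_pairs = pr$n_pairs,
               n_relevant = pr$n_relevant, proportion = pr$proportion,
               stringsAsFactors = FALSE)
  }))
  pairs <- list(c("derna", "non_derna"), c("strength", "non_strength"),
                c("mitochondrial_strength", "mitochondrial_non_strength"),
                c("lipid_strength", "lipid_non_strength"),
                c("fibrosis_strength", "fibrosis_non_strength"))
  comparisons <- do.call(rbind, lapply(pairs, function(p) {
    g1 <- groups[groups$group == p[1], ]; g2 <- groups[groups$group == p[2], ]
    if (g1$n_pairs == 0 || g2$n_pairs == 0) {
      message("comparison ", p[1], " vs ", p[2], " skipped: empty side")
      return(NULL)
    }
    zt <- two_proportion_ztest(g1$n_relevant, g1$n_pairs, g2$n_relevant, g2$n_pairs)
    r1 <- as.numeric(rho[, grp[[p[1]]], drop = FALSE])
    r2 <- as.numeric(rho[, grp[[p[2]]], drop = FALSE])
    ks <- ks_two_sample(r1[!is.na(r1)], r2[!is.na(r2)])
    data.frame(group1 = p[1], group2 = p[2],
               prop1 = g1$proportion, prop2 = g2$proportion,
               z_stat = zt$z, z_p = zt$p, z_p_display = zt$p_display,
               ks_D = ks$D, ks_p = ks$p,
               stringsAsFactors = FALSE)
  }))
  structure(list(groups = groups, comparisons = comparisons, tau = tau),
            class = "corr_enrichment")
}

#' @export
print.corr_enrichment <- function(x, ...) {
  cat("corr_enrichment (tau =", x$tau, ")\n\nGroup proportions of |rho| > tau:\n")
  g <- x$groups
  g$proportion <- round(100 * g$proportion, 1)
  names(g)[names(g) == "proportion"] <- "pct_relevant"
  print.data.frame(g, row.names = FALSE)
  if (!is.null(x$comparisons) && nrow(x$comparisons)) {
    cat("\nComparisons (two-proportion Z and KS):\n")
    cc <- x$comparisons
    cc$z_stat <- round(cc$z_stat, 2); cc$ks_D <- round(cc$ks_D, 3)
    cc$z_p <- NULL; cc$ks_p <- format_pvalue(x$comparisons$ks_p)
    print.data.frame(cc, row.names = FALSE)
  }
  invisible(x)
}

#' Plot group ECDFs of correlation coefficients
#'
#' Base-graphics ECDF curves of the rho distributions for a set of RNA
#' groups, the visual companion of the KS comparisons.
#'
#' @param x A `corr_enrichment` object is not needed; supply the raw rho
#'   matrix and labels instead.
#' @param rho Spearman correlation matrix.
#' @param groups Named list of logical column selectors.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
plot_rho_ecdf <- function(rho, groups, ...) {
  cols <- seq_along(groups) + 1
  first <- TRUE
  for (i in seq_along(groups)) {
    v <- as.numeric(rho[, groups[[i]], drop = FALSE])
    v <- v[!is.na(v)]
    e <- ecdf_table(v)
    if (first) {
      plot(e$value, e$cumprop, type = "s", col = cols[i], xlab = "rho",
           ylab = "cumulative proportion", xlim = c(-1, 1), ylim = c(0, 1), ...)
      first <- FALSE
    } else graphics::lines(e$value, e$cumprop, type = "s", col = cols[i])
  }
  graphics::legend("topleft", legend = names(groups), col = cols, lty = 1, bty = "n")
  invisible(NULL)
}
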