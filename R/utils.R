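# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive deterministic per-stage child seeds from one global seed
#'
#' A single cohort/pipeline seed is expanded into named child seeds, one per
#' stochastic stage, so that changing one stage's draws never perturbs the
#' others. Seeds stay below 2^31 - 1.
#'
#' @param seed Integer master seed.
#' @param stages Character vector of stage names.
#' @return Named integer vector of child seeds.
#' @keywords internal
child_seeds <- function(seed, stages) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  s <- sample.int(.Machine$integer.max - 1L, length(stages))
  names(s) <- stages
  s
}

# Run an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_proportion <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_field(field, "must be a single number in [0, 1]")
  invisible(x)
}

#' Vectorised ordinary least squares across many response columns
#'
#' Fits the same design matrix to every column of `Y` and returns per-column
#' coefficients, standard errors, t statistics and two-sided p-values. This is
#' the shared engine behind per-probe and per-RNA model fitting.
#'
#' @param Y Numeric matrix, samples x features (each column one response).
#' @param X Numeric design matrix, samples x coefficients, with column names.
#' @param drop_aliased If `TRUE`, columns of `X` made redundant by collinearity
#'   are dropped with a warning; if `FALSE`, rank deficiency is an error that
#'   names the offending columns.
#' @return List with matrices `coef`, `se`, `t`, `p` (coefficients x features),
#'   scalar `df`, and `dropped` (names of removed design columns).
#' @keywords internal
ols_fit_matrix <- function(Y, X, drop_aliased = FALSE) {
  stopifnot(is.matrix(Y), is.matrix(X), nrow(Y) == nrow(X))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  qrX <- qr(X)
  dropped <- character(0)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    if (!drop_aliased)
      stop("design matrix is rank deficient; collinear columns: ",
           paste(bad, collapse = ", "), call. = FALSE)
    warning("dropping aliased design columns: ", paste(bad, collapse = ", "),
            call. = FALSE)
    dropped <- bad
    X <- X[, setdiff(colnames(X), bad), drop = FALSE]
    qrX <- qr(X)
  }
  n <- nrow(X); p <- ncol(X)
  df <- n - p
  if (df <= 0) stop("non-positive residual degrees of freedom", call. = FALSE)
  coefs <- qr.coef(qrX, Y)                      # p x features
  fitted <- X %*% coefs
  rss <- colSums((Y - fitted)^2)
  sigma2 <- rss / df
  XtXinv_diag <- diag(chol2inv(qr.R(qrX)))[order(qrX$pivot)]
  names(XtXinv_diag) <- colnames(X)
  se <- sqrt(outer(XtXinv_diag, sigma2))
  tstat <- coefs / se
  pval <- 2 * stats::pt(-abs(tstat), df = df)
  rownames(se) <- rownames(tstat) <- rownames(pval) <- colnames(X)
  list(coef = coefs, se = se, t = tstat, p = pval, df = df, dropped = dropped)
}

# p-value floor rendering following the convention of reporting values below
# double-precision eps as "< 2.2e-16" while keeping the raw number machine-side.
format_pvalue <- function(p) {
  ifelse(p < 2.220446e-16, "< 2.2e-16", formatC(p, format = "g", digits = 3))
}
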