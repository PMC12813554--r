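#' Convert methylation beta-values to M-values
#'
#' The beta-value is the proportion of methylation at a CpG (0 = unmethylated,
#' 1 = fully methylated); the M-value is its log2 odds,
#' \eqn{M = \log_2(\beta/(1-\beta))}, the scale on which per-probe linear
#' models are fitted because variance is more homogeneous there. Values are
#' clamped into \eqn{[\epsilon, 1-\epsilon]} first so boundary betas do not
#' map to infinity.
#'
#' @param beta Numeric vector or matrix of beta-values in \[0, 1\].
#' @param clamp_eps Clamping bound, default `1e-6`.
#' @return M-values with the shape of `beta`.
#' @examples
#' beta_to_m(c(0.5, 0.8, 2/3))  # 0, 2, 1
#' @seealso [m_to_beta()]
#' @export
beta_to_m <- function(beta, clamp_eps = 1e-6) {
  if (!is.numeric(beta)) stop("'beta' must be numeric", call. = FALSE)
  rng <- range(beta, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
    stop("beta-values must lie in [0, 1]; got range [",
         signif(rng[1], 4), ", ", signif(rng[2], 4), "]", call. = FALSE)
  b <- pmin(pmax(beta, clamp_eps), 1 - clamp_eps)
  log2(b / (1 - b))
}

#' Convert M-values back to beta-values
#'
#' Inverse logistic transform \eqn{\beta = 2^M/(2^M + 1)}. Round-trips with
#' [beta_to_m()] to within 1e-9 for betas away from the clamping bound.
#'
#' @param m Numeric vector or matrix of finite M-values.
#' @return Beta-values in (0, 1) with the shape of `m`.
#' @export
m_to_beta <- function(m) {
  if (!is.numeric(m)) stop("'m' must be numeric", call. = FALSE)
  stats::plogis(m * log(2))
}
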