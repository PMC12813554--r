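#' Construct a methylation dataset
#'
#' Container for a probes x samples beta-value matrix with an optional
#' detection p-value matrix of identical shape. Beta-values are validated to
#' lie in (0, 1) (values exactly on the boundary are clamped inward by
#' `clamp_eps`); probe and sample identifiers must be unique.
#'
#' @param beta Numeric matrix, probes x samples, with rownames (probe ids)
#'   and colnames (sample ids).
#' @param detection_p Optional numeric matrix in \[0, 1\] with identical
#'   dimnames, the per-cell detection p-values.
#' @param clamp_eps Boundary clamp applied to beta-values, default `1e-6`.
#' @return An object of class `methylation_dataset` with elements `beta`,
#'   `detection_p`, `probe_ids`, `sample_ids`.
#' @export
methylation_dataset <- function(beta, detection_p = NULL, clamp_eps = 1e-6) {
  if (!is.matrix(beta) || !is.numeric(beta))
    stop("'beta' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop("'beta' must carry probe rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(beta)))
    stop("duplicate probe ids in beta matrix", call. = FALSE)
  if (anyDuplicated(colnames(beta)))
    stop("duplicate sample ids in beta matrix", call. = FALSE)
  if (anyNA(beta) || min(beta) < 0 || max(beta) > 1)
    stop("beta-values must be within [0, 1] and non-missing", call. = FALSE)
  beta <- pmin(pmax(beta, clamp_eps), 1 - clamp_eps)
  if (!is.null(detection_p)) {
    if (!identical(dim(detection_p), dim(beta)))
      stop("detection_p must have the same shape as beta", call. = FALSE)
    if (!identical(dimnames(detection_p), dimnames(beta)))
      stop("detection_p dimnames must match beta", call. = FALSE)
    if (anyNA(detection_p) || min(detection_p) < 0 || max(detection_p) > 1)
      stop("detection p-values must be within [0, 1]", call. = FALSE)
  }
  structure(
    list(beta = beta, detection_p = detection_p,
         probe_ids = rownames(beta), sample_ids = colnames(beta)),
    class = "methylation_dataset"
  )
}

#' @export
print.methylation_dataset <- function(x, ...) {
  cat("methylation_dataset:", nrow(x$beta), "probes x", ncol(x$beta), "samples\n")
  cat("  detection p matrix:", if (is.null(x$detection_p)) "absent" else "present", "\n")
  cat("  beta range:", paste(signif(range(x$beta), 4), collapse = " - "), "\n")
  invisible(x)
}

#' @export
dim.methylation_dataset <- function(x) dim(x$beta)

subset_probes <- function(ds, keep) {
  methylation_dataset(
    ds$beta[keep, , drop = FALSE],
    if (!is.null(ds$detection_p)) ds$detection_p[keep, , drop = FALSE] else NULL
  )
}

#' Remove probes with poor detection across samples
#'
#' Drops every probe whose detection p-value exceeds `p_threshold` in at least
#' `sample_fraction` of samples, i.e. probes whose signal is not reliably
#' distinguishable from background noise. The per-cell rule
#' (value > threshold, counted across samples) is applied exactly; probe order
#' is preserved.
#'
#' @param ds A [methylation_dataset()] carrying a detection p matrix.
#' @param p_threshold Detection p cut-off, default 0.01.
#' @param sample_fraction Fraction of samples at which a probe is failed,
#'   default 0.5.
#' @return The filtered `methylation_dataset`.
#' @export
filter_probes_by_detection <- function(ds, p_threshold = 0.01, sample_fraction = 0.5) {
  stopifnot(inherits(ds, "methylation_dataset"))
  if (is.null(ds$detection_p))
    stop("no detection_p matrix present; skip this filter explicitly if ",
         "detection p-values are unavailable", call. = FALSE)
  check_proportion(sample_fraction, "sample_fraction")
  frac_failed <- rowMeans(ds$detection_p > p_threshold)
  subset_probes(ds, frac_failed < sample_fraction)
}

#' Remove probes overlapping known SNPs
#'
#' Polymorphisms under a probe confound the methylation signal with genotype;
#' probes flagged as SNP-overlapping in the annotation are excluded.
#'
#' @param ds A [methylation_dataset()].
#' @param ann A probe annotation data frame as returned by
#'   [simulate_probe_annotation()] or [read_probe_annotation()], with columns
#'   `probe_id` and `snp_flag`. Every probe in `ds` must be annotated.
#' @return The filtered `methylation_dataset`.
#' @export
filter_snp_probes <- function(ds, ann) {
  stopifnot(inherits(ds, "methylation_dataset"))
  missing_ids <- setdiff(ds$probe_ids, ann$probe_id)
  if (length(missing_ids))
    stop("probes absent from annotation: ",
         paste(utils::head(missing_ids, 5), collapse = ", "),
         if (length(missing_ids) > 5) sprintf(" (and %d more)", length(missing_ids) - 5),
         call. = FALSE)
  flagged <- ann$probe_id[as.logical(ann$snp_flag)]
  subset_probes(ds, !(ds$probe_ids %in% flagged))
}

#' Stratified quantile normalisation of beta-values
#'
#' Classical quantile normalisation (each sample's values replaced by the mean
#' order statistics across samples, preserving within-sample ranks) applied
#' separately within probe strata, typically the Infinium probe-design type.
#' Operates on beta-values; the result is clamped back into (0, 1).
#'
#' @param ds A [methylation_dataset()].
#' @param strata Vector of stratum labels, one per probe, or a probe
#'   annotation data frame with columns `probe_id` and `probe_type`.
#' @return A normalised `methylation_dataset`.
#' @export
quantile_normalize_stratified <- function(ds, strata) {
  stopifnot(inherits(ds, "methylation_dataset"))
  if (is.data.frame(strata)) {
    idx <- match(ds$probe_ids, strata$probe_id)
    if (anyNA(idx)) stop("every probe needs a stratum assignment", call. = FALSE)
    strata <- strata$probe_type[idx]
  }
  if (length(strata) != nrow(ds$beta))
    stop("every probe needs a stratum assignment", call. = FALSE)
  out <- ds$beta
  for (s in unique(strata)) {
    rows <- which(strata == s)
    if (!length(rows)) {
      warning("empty stratum '", s, "' skipped", call. = FALSE)
      next
    }
    out[rows, ] <- limma::normalizeQuantiles(ds$beta[rows, , drop = FALSE])
  }
  out <- pmin(pmax(out, 1e-6), 1 - 1e-6)
  methylation_dataset(out, ds$detection_p)
}
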