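# Probe -> gene/region mapping: region distribution of DMPs and aggregation
# to differentially methylated genes with direction partition.

ann_links_for <- function(ann, probe_ids) {
  idx <- match(probe_ids, ann$probe_id)
  if (anyNA(idx))
    stop("unannotated probes: ",
         paste(utils::head(probe_ids[is.na(idx)], 5), collapse = ", "), call. = FALSE)
  ann$links[idx]
}

#' Summarise the genomic-region distribution of DMPs
#'
#' Counts DMPs per region category: promoter (any TSS200 or TSS1500 link),
#' 5'UTR, gene body, 3'UTR, and intergenic (no gene links). A probe counts at
#' most once per category, but a probe overlapping several transcript regions
#' is counted in each relevant category, so category counts can exceed the
#' number of DMPs. Percentages always use the total DMP count as denominator.
#'
#' @param dmps A `dmp_table` (or data frame with `probe_id`).
#' @param ann A `probe_annotation` covering every DMP.
#' @return A `region_summary` data frame with columns `region`, `count`,
#'   `percentage`, and attribute `denominator`.
#' @export
summarize_regions <- function(dmps, ann) {
  links <- ann_links_for(ann, dmps$probe_id)
  regs <- lapply(links, `[[`, "region_group")
  has <- function(groups) vapply(regs, function(r) any(r %in% groups), logical(1))
  counts <- c(promoter = sum(has(c("TSS200", "TSS1500"))),
              `5UTR` = sum(has("5UTR")),
              gene_body = sum(has("Body")),
              `3UTR` = sum(has("3UTR")),
              intergenic = sum(lengths(regs) == 0))
  denom <- nrow(dmps)
  out <- data.frame(region = names(counts), count = as.integer(counts),
                    percentage = if (denom) 100 * counts / denom else rep(NA_real_, 5),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "denominator") <- denom
  class(out) <- c("region_summary", "data.frame")
  out
}

#' Aggregate DMPs to differentially methylated genes
#'
#' A DMG is any gene linked to at least one DMP. Each gene is classed by the
#' directions of its DMPs: `hypo_only`, `hyper_only`, or `mixed`; the three
#' class counts always partition the DMG total.
#'
#' @param dmps A `dmp_table` with `probe_id` and `direction`.
#' @param ann A `probe_annotation` covering every DMP.
#' @return A `dmg_table` data frame with columns `gene_id`, `probe_ids`
#'   (list-column), `n_dmps`, `direction_class`.
#' @export
aggregate_dmgs <- function(dmps, ann) {
  links <- ann_links_for(ann, dmps$probe_id)
  n_links <- vapply(links, nrow, integer(1))
  if (!nrow(dmps) || sum(n_links) == 0) {
    out <- data.frame(gene_id = character(0), n_dmps = integer(0),
                      direction_class = character(0), stringsAsFactors = FALSE)
    out$probe_ids <- list()
    class(out) <- c("dmg_table", "data.frame")
    return(out)
  }
  long <- data.frame(
    gene_id = unlist(lapply(links, `[[`, "gene_id")),
    probe_id = rep(dmps$probe_id, n_links),
    direction = rep(dmps$direction, n_links),
    stringsAsFactors = FALSE)
  long <- unique(long)
  sp <- split(long, long$gene_id)
  out <- data.frame(
    gene_id = names(sp),
    n_dmps = vapply(sp, function(d) length(unique(d$probe_id)), integer(1)),
    direction_class = vapply(sp, function(d) {
      dirs <- unique(d$direction)
      if (length(dirs) > 1) "mixed" else if (dirs == "hypo") "hypo_only" else "hyper_only"
    }, character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out$probe_ids <- lapply(sp, function(d) unique(d$probe_id))
  class(out) <- c("dmg_table", "data.frame")
  out
}

#' @export
print.dmg_table <- function(x, ...) {
  tab <- table(factor(x$direction_class, c("hypo_only", "hyper_only", "mixed")))
  cat(sprintf("dmg_table: %d DMGs (%d hypo-only, %d hyper-only, %d mixed)\n",
              nrow(x), tab["hypo_only"], tab["hyper_only"], tab["mixed"]))
  invisible(x)
}

#' Split DMPs by methylation direction
#'
#' @param dmps A `dmp_table`.
#' @return List with probe-id sets `hypo`, `hyper`, `combined`.
#' @export
split_by_direction <- function(dmps) {
  list(hypo = dmps$probe_id[dmps$direction == "hypo"],
       hyper = dmps$probe_id[dmps$direction == "hyper"],
       combined = dmps$probe_id)
}
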