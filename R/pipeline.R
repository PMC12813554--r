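# End-to-end orchestration: simulate -> QC -> DMP -> annotate/enrich ->
# correlate -> risk factors, with per-stage logging to stderr, persisted
# plain-text artifacts, and a machine-readable JSON run report.

#' Configure a pipeline run
#'
#' @param out_dir Output directory for all artifacts.
#' @param input_dir Directory holding input files (`beta.tsv`,
#'   `detection_p.tsv`, `sample_sheet.csv`, `annotation.tsv`,
#'   `expression.tsv`, `rna_labels.tsv`) when `simulate = FALSE`.
#' @param simulate Generate a synthetic cohort instead of reading inputs.
#' @param sim_config A [cohort_config()] or argument list for it.
#' @param categories_gmt Optional GMT file of gene sets; enrichment runs when
#'   supplied.
#' @param detection_p_threshold,detection_sample_fraction Detection filter
#'   parameters.
#' @param fdr FDR threshold for DMP and DERNA calling.
#' @param tau Relevance threshold for |rho|.
#' @param risk_p Per-association significance threshold for risk factors.
#' @param normalize Apply stratified quantile normalisation before modelling.
#' @param moderate Use empirical-Bayes moderated t-statistics for DMPs.
#' @param patients_only_correlations Correlate over patients only instead of
#'   the full cohort.
#' @param relabel_rnas Re-derive DERNA/strength labels from the expression
#'   data instead of using provided labels.
#' @param factors Risk-factor column names; defaults to age/sex/bmi plus
#'   every exposure column found in the sample sheet.
#' @param seed Master seed.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, input_dir = NULL, simulate = TRUE,
                            sim_config = list(), categories_gmt = NULL,
                            detection_p_threshold = 0.01,
                            detection_sample_fraction = 0.5,
                            fdr = 0.05, tau = 0.3, risk_p = 0.05,
                            normalize = FALSE, moderate = FALSE,
                            patients_only_correlations = FALSE,
                            relabel_rnas = FALSE,
                            factors = NULL, seed = 1L) {
  check_proportion(detection_p_threshold, "detection_p_threshold")
  check_proportion(detection_sample_fraction, "detection_sample_fraction")
  check_proportion(fdr, "fdr")
  check_proportion(risk_p, "risk_p")
  if (tau < 0 || tau >= 1) stop_field("tau", "must lie in [0, 1)")
  cfg <- list(out_dir = out_dir, input_dir = input_dir, simulate = simulate,
              sim_config = sim_config, categories_gmt = categories_gmt,
              detection_p_threshold = detection_p_threshold,
              detection_sample_fraction = detection_sample_fraction,
              fdr = fdr, tau = tau, risk_p = risk_p, normalize = normalize,
              moderate = moderate,
              patients_only_correlations = patients_only_correlations,
              relabel_rnas = relabel_rnas, factors = factors,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path Path to a YAML file with [pipeline_config()] fields.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Validate a set of pipeline input files
#'
#' Structural checks (id uniqueness, shape agreement between matrices and
#' sample sheet, RNA label invariants) returning diagnostics rather than
#' raising errors.
#'
#' @param input_dir Directory holding the input files.
#' @return Data frame of violations (`check`, `detail`); zero rows when clean.
#' @export
validate_inputs <- function(input_dir) {
  v <- list()
  add <- function(check, detail) v[[length(v) + 1L]] <<- data.frame(
    check = check, detail = detail, stringsAsFactors = FALSE)
  p <- function(f) file.path(input_dir, f)
  for (f in c("beta.tsv", "sample_sheet.csv", "annotation.tsv"))
    if (!file.exists(p(f))) add("missing_file", p(f))
  if (length(v)) return(do.call(rbind, v))
  ds <- tryCatch(read_methylation_dataset(p("beta.tsv"),
                   if (file.exists(p("detection_p.tsv"))) p("detection_p.tsv") else NULL),
                 error = function(e) { add("beta_matrix", conditionMessage(e)); NULL })
  sheet <- tryCatch(read_sample_sheet(p("sample_sheet.csv")),
                    error = function(e) { add("sample_sheet", conditionMessage(e)); NULL })
  ann <- tryCatch(read_probe_annotation(p("annotation.tsv")),
                  error = function(e) { add("annotation", conditionMessage(e)); NULL })
  if (!is.null(ds) && !is.null(sheet) &&
      !setequal(ds$sample_ids, sheet$sample_id))
    add("sample_mismatch", "beta matrix and sample sheet sample ids differ")
  if (!is.null(ds) && !is.null(ann)) {
    nmiss <- length(setdiff(ds$probe_ids, ann$probe_id))
    if (nmiss) add("annotation_coverage", paste(nmiss, "probes unannotated"))
  }
  if (file.exists(p("expression.tsv"))) {
    ex <- tryCatch(read_expression_dataset(p("expression.tsv"),
                     if (file.exists(p("rna_labels.tsv"))) p("rna_labels.tsv") else NULL),
                   error = function(e) { add("expression", conditionMessage(e)); NULL })
    if (!is.null(ex) && !is.null(sheet) &&
        !setequal(colnames(ex$expr), sheet$sample_id))
      add("expression_sample_mismatch",
          "expression matrix and sample sheet sample ids differ")
  }
  if (length(v)) do.call(rbind, v) else
    data.frame(check = character(0), detail = character(0), stringsAsFactors = FALSE)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> QC filters -> per-probe DMP models ->
#' region/gene annotation (and enrichment when gene sets are supplied) ->
#' methylation-expression correlation enrichment -> risk-factor association,
#' writing every artifact as plain text under `config$out_dir` before the
#' next stage reads it. Identical configuration and seed produce identical
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` list with per-stage dimensions, counts and
#'   statistics; also written as `report.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed, stages = list())
  p <- function(f) file.path(config$out_dir, f)

  ## stage: simulate or load
  if (config$simulate) {
    cohort <- run_stage("simulate", {
      sc <- config$sim_config
      if (!inherits(sc, "cohort_config")) {
        sc$seed <- sc$seed %||% config$seed
        sc <- do.call(cohort_config, sc)
      }
      simulate_cohort(sc)
    })
    run_stage("simulate", write_cohort(cohort, p("simulated")))
    log_stage("simulate", "cohort of ", nrow(cohort$sheet), " samples, ",
              nrow(cohort$methylation$beta), " probes")
  } else {
    cohort <- run_stage("load", {
      if (is.null(config$input_dir)) stop("no input_dir configured")
      ind <- config$input_dir
      need <- file.path(ind, c("beta.tsv", "sample_sheet.csv", "annotation.tsv",
                               "expression.tsv"))
      miss <- need[!file.exists(need)]
      if (length(miss)) stop("missing input file(s): ", paste(miss, collapse = ", "))
      detp <- file.path(ind, "detection_p.tsv")
      lab <- file.path(ind, "rna_labels.tsv")
      ex <- read_expression_dataset(file.path(ind, "expression.tsv"),
                                    if (file.exists(lab)) lab else NULL)
      list(methylation = read_methylation_dataset(file.path(ind, "beta.tsv"),
             if (file.exists(detp)) detp else NULL),
           sheet = read_sample_sheet(file.path(ind, "sample_sheet.csv")),
           annotation = read_probe_annotation(file.path(ind, "annotation.tsv")),
           expression = ex, truth = NULL)
    })
  }
  report$stages$input <- list(n_probes = nrow(cohort$methylation$beta),
                              n_samples = ncol(cohort$methylation$beta),
                              n_rnas = nrow(cohort$expression$expr))

  ## stage: qc
  ds <- run_stage("qc", {
    d <- cohort$methylation
    n0 <- nrow(d$beta)
    if (!is.null(d$detection_p))
      d <- filter_probes_by_detection(d, config$detection_p_threshold,
                                      config$detection_sample_fraction)
    n1 <- nrow(d$beta)
    d <- filter_snp_probes(d, cohort$annotation)
    n2 <- nrow(d$beta)
    if (config$normalize)
      d <- quantile_normalize_stratified(d, cohort$annotation)
    log_stage("qc", n0, " probes; ", n0 - n1, " failed detection; ",
              n1 - n2, " SNP-flagged; ", n2, " retained")
    report$stages$qc <- list(probes_in = n0, failed_detection = n0 - n1,
                              snp_removed = n1 - n2, probes_retained = n2)
    d
  })
  run_stage("qc", write_methylation_dataset(ds, p("beta_filtered.tsv")))

  ## stage: dmp
  dmps <- run_stage("dmp", {
    M <- beta_to_m(ds$beta)
    fit <- fit_dmp_models(M, cohort$sheet, moderate = config$moderate)
    call_dmps(fit, ds$beta, cohort$sheet, fdr = config$fdr)
  })
  run_stage("dmp", write_dmp_table(dmps, p("dmps.tsv"), p("dmp_summary.json")))
  log_stage("dmp", nrow(dmps), " DMPs at FDR < ", config$fdr)
  report$stages$dmp <- attr(dmps, "summary")

  ## stage: annotate (+ optional enrichment)
  run_stage("annotate", {
    regions <- summarize_regions(dmps, cohort$annotation)
    dmgs <- aggregate_dmgs(dmps, cohort$annotation)
    utils::write.table(as.data.frame(regions), p("region_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dmg_out <- as.data.frame(dmgs[, c("gene_id", "n_dmps", "direction_class")])
    utils::write.table(dmg_out, p("dmgs.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    cls <- table(factor(dmgs$direction_class, c("hypo_only", "hyper_only", "mixed")))
    report$stages$annotate <- list(
      region_counts = stats::setNames(as.list(regions$count), regions$region),
      n_dmgs = nrow(dmgs),
      dmg_partition = as.list(cls))
    log_stage("annotate", nrow(dmgs), " DMGs (", cls[1], " hypo-only, ",
              cls[2], " hyper-only, ", cls[3], " mixed)")
    if (!is.null(config$categories_gmt)) {
      categories <- read_gmt(config$categories_gmt)
      sets <- split_by_direction(dmps)
      all_probes <- ds$probe_ids
      enr <- list()
      for (side in names(sets)) {
        if (!length(sets[[side]])) next
        side_dmps <- dmps[dmps$probe_id %in% sets[[side]], , drop = FALSE]
        side_genes <- aggregate_dmgs(side_dmps, cohort$annotation)$gene_id
        uni <- unique(unlist(lapply(ann_links_for(cohort$annotation, all_probes),
                                    `[[`, "gene_id")))
        eg <- ora_hypergeometric(intersect(side_genes, uni), uni, categories)
        ep <- ora_probe_bias(sets[[side]], all_probes, cohort$annotation, categories)
        ep$odds <- NULL
        eg$side <- ep$side <- side
        enr[[side]] <- rbind(eg, ep)
      }
      if (length(enr))
        utils::write.table(do.call(rbind, enr), p("enrichment.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
    }
  })

  ## stage: correlate
  corr <- run_stage("correlate", {
    expr <- cohort$expression$expr
    labels <- cohort$expression$labels
    if (is.null(labels) || config$relabel_rnas) {
      derna <- label_dernas(expr, cohort$sheet, fdr = config$fdr)
      pat <- cohort$sheet$group[match(colnames(expr), cohort$sheet$sample_id)] == "patient"
      strength <- cohort$sheet$strength[match(colnames(expr), cohort$sheet$sample_id)]
      sa <- label_strength_association(expr, strength, derna, pat, fdr = config$fdr)
      labels <- data.frame(rna_id = rownames(expr), derna = unname(derna),
                           strength_associated = unname(sa),
                           pathway = "none", stringsAsFactors = FALSE)
    }
    cols <- cohort$sheet$sample_id
    if (config$patients_only_correlations)
      cols <- cohort$sheet$sample_id[cohort$sheet$group == "patient"]
    if (!nrow(dmps)) {
      log_stage("correlate", "no DMPs; stage skipped")
      return(NULL)
    }
    rho <- spearman_matrix(ds$beta[dmps$probe_id, cols, drop = FALSE],
                           expr[, cols, drop = FALSE])
    compare_rna_groups(rho, labels, tau = config$tau)
  })
  if (!is.null(corr)) {
    utils::write.table(corr$groups, p("correlation_groups.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(corr$comparisons))
      utils::write.table(corr$comparisons, p("correlation_comparisons.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$correlate <- list(groups = corr$groups,
                                    comparisons = corr$comparisons)
    log_stage("correlate", nrow(corr$groups), " RNA groups compared")
  }

  ## stage: risk factors
  risk <- run_stage("riskfactors", {
    if (!nrow(dmps)) return(NULL)
    factors <- config$factors
    if (is.null(factors)) {
      std <- c("sample_id", "group", "age", "sex", "bmi", "strength")
      factors <- c("age", "sex", "bmi", setdiff(names(cohort$sheet), std))
    }
    res <- fit_risk_models(ds$beta[dmps$probe_id, , drop = FALSE], cohort$sheet,
                           factors, dmps, p_threshold = config$risk_p)
    utils::write.table(as.data.frame(res), p("risk_associations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    fs <- summarize_factors(res)
    utils::write.table(fs, p("risk_factor_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(fs, p("risk_factor_summary.json"), auto_unbox = TRUE,
                         digits = NA)
    log_stage("riskfactors", sum(res$significant), " significant associations")
    list(n_associations = sum(res$significant), summary = fs)
  })
  if (!is.null(risk))
    report$stages$riskfactors <- list(n_associations = risk$n_associations)

  report$wall_time_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  report$config_hash <- sum(utf8ToInt(paste(utils::capture.output(
    utils::str(unclass(config))), collapse = "")))
  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  class(report) <- "run_report"
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (seed", x$seed, ")\n")
  for (s in names(x$stages)) {
    st <- x$stages[[s]]
    parts <- vapply(names(st), function(nm) {
      v <- st[[nm]]
      if (is.data.frame(v)) sprintf("%s=<%d rows>", nm, nrow(v))
      else paste0(nm, "=", paste(format(unlist(v)), collapse = "/"))
    }, "")
    cat("  ", s, ": ", paste(parts, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
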