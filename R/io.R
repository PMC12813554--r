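# Readers and writers for the plain-text interchange formats: TSV matrices
# (probes/RNAs as rows, first column the id), CSV sample sheets, TSV probe
# annotations with a packed `gene_links` column, and GMT category files.

read_id_matrix <- function(path, id_col = 1L) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[id_col]])
  if (anyDuplicated(ids))
    stop("duplicate row ids in ", path, call. = FALSE)
  m <- as.matrix(df[, -id_col, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (anyDuplicated(colnames(m)))
    stop("duplicate column ids in ", path, call. = FALSE)
  m
}

write_id_matrix <- function(m, path, id_name = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a beta-value (or detection-p) matrix from TSV
#'
#' Probes as rows with the probe id in the first column, samples as the
#' remaining header columns. Duplicate probe or sample ids are rejected.
#'
#' @param beta_path Path to the beta-value TSV.
#' @param detection_path Optional path to a detection-p TSV of the same shape.
#' @return A [methylation_dataset()].
#' @export
read_methylation_dataset <- function(beta_path, detection_path = NULL) {
  beta <- read_id_matrix(beta_path)
  detp <- if (!is.null(detection_path)) read_id_matrix(detection_path) else NULL
  if (!is.null(detp)) detp <- detp[rownames(beta), colnames(beta), drop = FALSE]
  methylation_dataset(beta, detp)
}

#' Write a methylation dataset to TSV files
#'
#' @param ds A [methylation_dataset()].
#' @param beta_path Output path for the beta matrix.
#' @param detection_path Optional output path for the detection-p matrix.
#' @return Invisibly, `beta_path`.
#' @export
write_methylation_dataset <- function(ds, beta_path, detection_path = NULL) {
  write_id_matrix(ds$beta, beta_path, "probe_id")
  if (!is.null(detection_path) && !is.null(ds$detection_p))
    write_id_matrix(ds$detection_p, detection_path, "probe_id")
  invisible(beta_path)
}

#' Read a sample sheet from CSV
#'
#' Required columns: `sample_id`, `group` (patient/control), `age`, `sex`
#' (male/female), `bmi`. Additional columns (exposures, strength measures)
#' pass through untouched. Missing values in the required columns and
#' duplicate sample ids are rejected.
#'
#' @param path Path to the CSV file.
#' @return A data frame with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

validate_sample_sheet <- function(df) {
  need <- c("sample_id", "group", "age", "sex", "bmi")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample sheet is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in sample sheet", call. = FALSE)
  for (col in need)
    if (anyNA(df[[col]]))
      stop_field(col, "sample sheet column contains missing values")
  if (!all(df$group %in% c("patient", "control")))
    stop_field("group", "values must be 'patient' or 'control'")
  if (!all(df$sex %in% c("male", "female")))
    stop_field("sex", "values must be 'male' or 'female'")
  df
}

#' Write a sample sheet to CSV
#' @param sheet Sample sheet data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Gene links are packed as "gene:region" pairs separated by ";", empty for
# intergenic probes, mirroring the multi-entry RefGene columns of Illumina
# manifests.
pack_links <- function(links) {
  vapply(links, function(l) {
    if (!nrow(l)) "" else paste(paste0(l$gene_id, ":", l$region_group), collapse = ";")
  }, character(1))
}

unpack_links <- function(s) {
  lapply(s, function(x) {
    if (is.na(x) || !nzchar(x))
      return(data.frame(gene_id = character(0), region_group = character(0),
                        stringsAsFactors = FALSE))
    parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    data.frame(gene_id = vapply(parts, `[`, "", 1),
               region_group = vapply(parts, `[`, "", 2),
               stringsAsFactors = FALSE)
  })
}

#' Read a probe annotation table from TSV
#'
#' Columns: `probe_id`, `chromosome`, `position`, `gene_links` (packed
#' `gene:region` pairs separated by `;`, empty for intergenic probes),
#' `snp_flag`, `probe_type`.
#'
#' @param path Path to the annotation TSV.
#' @return A `probe_annotation` data frame with a `links` list-column.
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(gene_links = "character"))
  if (anyDuplicated(df$probe_id))
    stop("duplicate probe ids in annotation", call. = FALSE)
  df$snp_flag <- as.logical(df$snp_flag)
  df$links <- unpack_links(df$gene_links)
  check_region_vocab(df)
  class(df) <- c("probe_annotation", "data.frame")
  df
}

region_vocabulary <- c("TSS200", "TSS1500", "5UTR", "Body", "3UTR")

check_region_vocab <- function(ann) {
  regs <- unique(unlist(lapply(ann$links, `[[`, "region_group")))
  bad <- setdiff(regs, region_vocabulary)
  if (length(bad))
    stop("unknown gene-region groups: ", paste(bad, collapse = ", "), call. = FALSE)
  invisible(ann)
}

#' Write a probe annotation table to TSV
#' @param ann A `probe_annotation` data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_probe_annotation <- function(ann, path) {
  out <- data.frame(probe_id = ann$probe_id, chromosome = ann$chromosome,
                    position = ann$position, gene_links = pack_links(ann$links),
                    snp_flag = ann$snp_flag, probe_type = ann$probe_type,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene-set categories from a GMT file
#'
#' One category per line: id, description, then member genes, tab-separated.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 50), call. = FALSE)
    unique(parts[-(1:2)])
  })
  names(out) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  out
}

#' Write gene-set categories to a GMT file
#' @param categories Named list of character vectors of gene ids.
#' @param path Output path.
#' @param descriptions Optional character vector of descriptions.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(categories, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(categories))
  lines <- mapply(function(id, desc, genes)
    paste(c(id, desc, genes), collapse = "\t"),
    names(categories), descriptions, categories)
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix and optional RNA labels
#'
#' @param expr_path TSV with RNAs as rows (first column `rna_id`), samples as
#'   columns; values are assumed normalised, log-scale.
#' @param labels_path Optional TSV with columns `rna_id`, `derna`,
#'   `strength_associated`, `pathway`.
#' @return List with `expr` matrix and `labels` data frame (or `NULL`).
#' @export
read_expression_dataset <- function(expr_path, labels_path = NULL) {
  expr <- read_id_matrix(expr_path)
  labels <- NULL
  if (!is.null(labels_path)) {
    labels <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
    labels$derna <- as.logical(labels$derna)
    labels$strength_associated <- as.logical(labels$strength_associated)
    validate_rna_labels(labels)
  }
  list(expr = expr, labels = labels)
}

validate_rna_labels <- function(labels) {
  if (any(labels$strength_associated & !labels$derna))
    stop("strength_associated RNAs must be DERNAs", call. = FALSE)
  if (any(labels$pathway != "none" & !labels$derna))
    stop("pathway-labelled RNAs must be DERNAs", call. = FALSE)
  ok <- c("mitochondrial", "lipid", "fibrosis", "none")
  if (!all(labels$pathway %in% ok))
    stop("unknown pathway labels: ",
         paste(setdiff(unique(labels$pathway), ok), collapse = ", "), call. = FALSE)
  labels
}
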