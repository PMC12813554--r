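# Region summaries, DMG aggregation with direction partition, and
# over-representation analyses (hypergeometric and probe-bias Wallenius).

mk_ann <- function(probe_ids, links, snp = FALSE) {
  ann <- data.frame(probe_id = probe_ids,
                    chromosome = "1", position = seq_along(probe_ids),
                    snp_flag = snp, probe_type = "II",
                    stringsAsFactors = FALSE)
  ann$links <- links
  class(ann) <- c("probe_annotation", "data.frame")
  ann
}
lk <- function(genes, regions) data.frame(gene_id = genes, region_group = regions,
                                          stringsAsFactors = FALSE)
mk_dmps <- function(ids, directions) {
  d <- data.frame(probe_id = ids, direction = directions, stringsAsFactors = FALSE)
  class(d) <- c("dmp_table", "data.frame")
  d
}

test_that("a multi-region probe is counted once in each relevant category", {
  ann <- mk_ann("cg1", list(lk(c("G1", "G2"), c("TSS200", "Body"))))
  rs <- summarize_regions(mk_dmps("cg1", "hypo"), ann)
  counts <- setNames(rs$count, rs$region)
  expect_identical(counts[["promoter"]], 1L)
  expect_identical(counts[["gene_body"]], 1L)
  expect_identical(counts[["intergenic"]], 0L)
  expect_identical(attr(rs, "denominator"), 1L)
  expect_equal(rs$percentage[rs$region %in% c("promoter", "gene_body")],
               c(100, 100))
})

test_that("all-intergenic DMPs give a 100% intergenic summary", {
  empty <- lk(character(0), character(0))
  ann <- mk_ann(c("cg1", "cg2"), list(empty, empty))
  rs <- summarize_regions(mk_dmps(c("cg1", "cg2"), c("hypo", "hyper")), ann)
  expect_equal(setNames(rs$percentage, rs$region)[["intergenic"]], 100)
  expect_true(all(rs$count[rs$region != "intergenic"] == 0))
})

test_that("intergenic plus linked DMPs always partition the denominator", {
  co <- small_cohort(seed = 13)
  ids <- co$annotation$probe_id[1:150]
  dmps <- mk_dmps(ids, sample(c("hypo", "hyper"), 150, replace = TRUE))
  rs <- summarize_regions(dmps, co$annotation)
  counts <- setNames(rs$count, rs$region)
  n_linked <- sum(vapply(ann_links <- co$annotation$links[
    match(ids, co$annotation$probe_id)], nrow, integer(1)) > 0)
  expect_identical(unname(counts[["intergenic"]]) + n_linked,
                   attr(rs, "denominator"))
  expect_error(summarize_regions(mk_dmps("nope", "hypo"), co$annotation),
               "unannotated")
})

test_that("DMG aggregation partitions genes by direction class", {
  ann <- mk_ann(paste0("cg", 1:4),
                list(lk("G1", "TSS200"), lk("G1", "Body"),
                     lk("G2", "Body"), lk(c("G3", "G2"), c("3UTR", "5UTR"))))
  dmps <- mk_dmps(paste0("cg", 1:4), c("hypo", "hyper", "hypo", "hypo"))
  dmg <- aggregate_dmgs(dmps, ann)
  cls <- setNames(dmg$direction_class, dmg$gene_id)
  expect_identical(cls[["G1"]], "mixed")
  expect_identical(cls[["G2"]], "hypo_only")
  expect_identical(cls[["G3"]], "hypo_only")
  expect_identical(setNames(dmg$n_dmps, dmg$gene_id)[["G2"]], 2L)
  # partition identity on simulated data
  co <- small_cohort(seed = 17)
  ids <- co$annotation$probe_id[1:200]
  sim_dmps <- mk_dmps(ids, sample(c("hypo", "hyper"), 200, replace = TRUE))
  sim_dmg <- aggregate_dmgs(sim_dmps, co$annotation)
  tab <- table(factor(sim_dmg$direction_class,
                      c("hypo_only", "hyper_only", "mixed")))
  expect_identical(sum(tab), nrow(sim_dmg))
  expect_gt(nrow(sim_dmg), 0)
})

test_that("split_by_direction covers the DMP set", {
  dmps <- mk_dmps(paste0("cg", 1:5), c("hypo", "hypo", "hyper", "hyper", "hyper"))
  s <- split_by_direction(dmps)
  expect_identical(length(s$hypo), 2L)
  expect_identical(length(s$hyper), 3L)
  expect_identical(sort(c(s$hypo, s$hyper)), sort(s$combined))
  s0 <- split_by_direction(mk_dmps(character(0), character(0)))
  expect_identical(lengths(s0), c(hypo = 0L, hyper = 0L, combined = 0L))
})

test_that("hypergeometric ORA matches exact enumeration", {
  universe <- paste0("G", 1:10)
  categories <- list(cat5 = paste0("G", 1:5), all = universe,
                     disjoint = paste0("G", 8:10))
  res <- ora_hypergeometric(paste0("G", 1:3), universe, categories)
  p <- setNames(res$p_value, res$category_id)
  expect_equal(p[["cat5"]], choose(5, 3) / choose(10, 3))  # 10/120
  expect_equal(p[["all"]], 1)
  res2 <- ora_hypergeometric(paste0("G", 1:3), universe,
                             list(disjoint = paste0("G", 8:10)))
  expect_equal(res2$p_value, 1)  # upper tail includes overlap 0
  expect_error(ora_hypergeometric("G1", character(0), categories), "empty")
  expect_error(ora_hypergeometric("X9", universe, categories), "subset")
})

test_that("Wallenius pmf reduces to the central hypergeometric at omega 1", {
  for (N in c(5, 9, 12)) for (K in c(2, floor(N / 2))) for (n in c(2, N - 1)) {
    ks <- max(0, n - (N - K)):min(n, K)
    expect_equal(dwallenius(ks, N, K, n, 1), dhyper(ks, K, N - K, n),
                 tolerance = 1e-9)
  }
})

test_that("Wallenius tail matches enumeration of weighted draws", {
  # 6 genes, probe counts {1,1,1,3,3,3}; category = the heavy genes; omega 3
  w <- c(1, 1, 1, 3, 3, 3)
  for (k in 1:3) {
    expect_equal(pwallenius_upper(k, N = 6, K = 3, n = 3, omega = 3),
                 oracle_wallenius_tail(w, category = 4:6, n = 3, k = k),
                 tolerance = 1e-3)
  }
  # omega -> infinity: category members are drawn first, deterministically
  expect_equal(pwallenius_upper(3, N = 10, K = 3, n = 5, omega = 1e6), 1,
               tolerance = 1e-3)
  expect_lt(pwallenius_upper(1, N = 10, K = 3, n = 2, omega = 1e-6), 1e-3)
})

test_that("probe-bias ORA reduces to gene ORA for equal probe counts", {
  # build an annotation where every gene has exactly one probe
  n <- 60
  ids <- sprintf("p%03d", 1:n)
  links <- lapply(1:n, function(i) lk(sprintf("G%03d", i), "Body"))
  ann1 <- mk_ann(ids, links)
  categories <- list(a = sprintf("G%03d", 1:20), b = sprintf("G%03d", 15:40))
  sel <- ids[c(1:8, 30:34)]
  pb <- ora_probe_bias(sel, ids, ann1, categories)
  gg <- ora_hypergeometric(sprintf("G%03d", c(1:8, 30:34)), sprintf("G%03d", 1:n),
                           categories)
  expect_equal(pb$p_value, gg$p_value, tolerance = 1e-6)
  # a category with no genes in the universe is skipped with a warning
  expect_warning(
    res <- ora_probe_bias(sel, ids, ann1, c(categories, list(none = "ZZZ"))),
    "skipped")
  expect_identical(nrow(res), 2L)
  # genes with many probes raise the in-category odds above 1
  ids2 <- c(ids, sprintf("q%03d", 1:40))
  links3 <- c(links, lapply(1:40, function(i) lk(sprintf("G%03d", (i %% 20) + 1), "Body")))
  ann3 <- mk_ann(ids2, links3)
  pb3 <- ora_probe_bias(sel, ids2, ann3, categories["a"])
  expect_gt(pb3$odds, 1)
})

test_that("GMT files round-trip and drive enrichment end to end", {
  dir <- withr::local_tempdir()
  cats <- list(musc = c("G001", "G002", "G003"), vasc = c("G004", "G005"))
  path <- file.path(dir, "sets.gmt")
  write_gmt(cats, path, descriptions = c("muscle", "vessel"))
  expect_identical(read_gmt(path), cats)
  expect_error(read_gmt(writeLines("bad line", con = file.path(dir, "x.gmt")) %||%
                          file.path(dir, "x.gmt")), "malformed")
  # enrichment stage runs when categories are supplied to the pipeline
  co <- simulate_cohort(cohort_config(n_patients = 30, n_controls = 12,
                                      n_probes = 200, n_rnas = 80,
                                      frac_true_dmps = 0.2,
                                      mean_abs_delta_beta = 0.1, seed = 3))
  genes <- unique(unlist(lapply(co$annotation$links, `[[`, "gene_id")))
  write_gmt(list(setA = genes[1:10], setB = genes[5:20]), path)
  out <- withr::local_tempdir()
  cfg <- pipeline_config(out_dir = out, simulate = TRUE,
                         sim_config = list(n_patients = 30, n_controls = 12,
                                           n_probes = 200, n_rnas = 80,
                                           frac_true_dmps = 0.2,
                                           mean_abs_delta_beta = 0.1),
                         categories_gmt = path, seed = 3)
  suppressMessages(suppressWarnings(run_pipeline(cfg)))
  expect_true(file.exists(file.path(out, "enrichment.tsv")))
  enr <- utils::read.delim(file.path(out, "enrichment.tsv"))
  expect_setequal(unique(enr$method), c("hypergeometric", "wallenius"))
  expect_true(all(enr$p_value > 0 & enr$p_value <= 1))
})
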