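# musclemeth

Differential DNA-methylation analysis of skeletal muscle in former
intensive-care patients versus healthy controls, packaged as a reusable,
fully tested pipeline. The scientific question it serves: does critical
illness leave a lasting methylation imprint in muscle, do those
differentially methylated positions (DMPs) track differentially expressed
RNAs (DERNAs) and reduced muscle strength, and which clinical exposures
associate with more abnormal methylation?

Because cohort data of this kind are protected, the package ships a seeded
synthetic-cohort generator that reproduces the statistical structure the
analysis assumes — bimodal beta-values, planted group shifts, covariate
confounding, methylation-coupled expression, a strength phenotype driven by
a co-expressed RNA module, and exposure effects — together with ground-truth
labels, so every stage runs and is validated end to end with no downloads.

## The statistics at the core

* **Per-CpG models.** For each probe, OLS of the M-value
  (M = log2(β/(1−β))) on `[1, group, age, sex, BMI]`; two-sided t-test on
  the group coefficient (patients − controls); Benjamini–Hochberg FDR
  across retained probes; DMP at q < 0.05 with direction from sign(ΔM) and
  effect size 100·(β̄_patients − β̄_controls).
* **Region/gene aggregation.** Promoter = TSS200 ∪ TSS1500; a multi-region
  probe counts once per relevant category; DMGs (genes with ≥ 1 DMP) are
  partitioned hypo-only / hyper-only / mixed.
* **Probe-bias pathway enrichment.** Gene-level upper-tail hypergeometric
  ORA, plus a Wallenius noncentral hypergeometric variant with odds
  ω = mean probe count of in-category genes / mean probe count of
  out-of-category genes, correcting for genes that carry many probes.
* **Correlation enrichment.** Spearman ρ between every DMP and every RNA;
  per RNA group, the proportion of pairs with |ρ| > 0.3; groups compared
  with pooled two-proportion Z-tests and asymptotic two-sample
  Kolmogorov–Smirnov tests on the full ρ distributions.
* **Risk factors.** Per DMP, one joint OLS of the beta-value on all
  candidate exposures (patients only); a significant association is
  *harmful* if higher exposure pushes methylation further from control
  levels (coefficient < 0 on a hypomethylated DMP or > 0 on a
  hypermethylated one), *protective* otherwise.

## Worked example

```r
library(musclemeth)

cohort <- simulate_cohort(cohort_config(seed = 42))
ds  <- filter_snp_probes(filter_probes_by_detection(cohort$methylation),
                         cohort$annotation)
fit  <- fit_dmp_models(beta_to_m(ds$beta), cohort$sheet)
dmps <- call_dmps(fit, ds$beta, cohort$sheet, fdr = 0.05)
dmps
#> dmp_table: 68 DMPs (57.4% hypo, 42.6% hyper)
#>   |effect size|: mean 5.78%, max 17.89%

rho    <- spearman_matrix(ds$beta[dmps$probe_id, ], cohort$expression$expr)
enrich <- compare_rna_groups(rho, cohort$expression$labels)
enrich
#> Group proportions of |rho| > tau:
#>      group n_rnas n_pairs n_relevant pct_relevant
#>      derna     42    2856        903         31.6
#>  non_derna   1958  133144         37          0.0
#>  ...
#> Comparisons (two-proportion Z and KS):
#>  group1     group2     prop1     prop2      z_stat z_p_display  ks_D  ks_p
#>  derna      non_derna  0.3161765 0.0002779  201.62  < 2.2e-16   0.335 < 2.2e-16
```

Reading the output: of 1942 QC-retained probes, 68 are DMPs at FDR < 0.05,
mostly hypomethylated, with beta-scale effect sizes up to ~18 percentage
points. Correlations between DMP methylation and RNA expression exceed
|ρ| > 0.3 for 31.6% of DMP–DERNA pairs versus 0.03% of DMP–non-DERNA
pairs — the planted methylation–expression coupling recovered as a large,
decisively significant proportion gap.

The whole chain, including region summaries, enrichment, correlation and
risk-factor stages with all artifacts written as TSV/JSON:

```r
report <- run_pipeline(pipeline_config(out_dir = "run1", seed = 1))
```

or from a shell:

```sh
Rscript inst/cli/musclemeth.R run-all --out run1 --seed 1
```

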