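---
title: "Models and methods behind musclemeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind musclemeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musclemeth)
```

# The analysis problem

Survivors of a prolonged intensive-care stay often show muscle weakness that
persists for years. One candidate mechanism is a lasting epigenetic imprint:
DNA methylation changes in skeletal muscle that outlive the acute illness and
keep muscle gene programs dysregulated. The analysis chain implemented here
compares genome-scale CpG methylation (Infinium EPIC-style beta-values)
between former patients and healthy controls, annotates the differential
positions to genes and genomic regions, tests pathway over-representation
with a probe-count bias correction, asks whether differentially methylated
positions (DMPs) correlate with differentially expressed RNAs (DERNAs)
more than with unaffected RNAs, and finally screens clinical exposures for
directional associations with the abnormal methylation.

Because cohort methylation data of this kind are protected and typically not
redistributable, the package is built around a synthetic-cohort generator
that reproduces the *statistical structure* the analysis assumes, together
with ground-truth labels. Every pipeline stage is validated against that
generator; nothing in the package requires external data.

# Scales: beta-values and M-values

A beta-value is the methylated fraction at a CpG, in $[0,1]$. The M-value is
its log2 odds, $M = \log_2\big(\beta/(1-\beta)\big)$. Group comparisons are
fitted on M-values, where variance is approximately constant across the
range; effect sizes are reported on the beta scale (percentage-point
methylation differences), which is what practitioners interpret. The
transform is clamped at `clamp_eps = 1e-6` so simulated betas at the
boundary cannot produce infinite M-values; raw-intensity data, from which
betas are usually computed, cannot reach the boundary, so the clamp only
matters for simulated or rounded inputs. Because the transform is strictly
monotone, rank statistics are unaffected: Spearman correlations computed on
beta and on M are identical, which the tests assert exactly.

# Probe quality control

Two filters mirror standard array practice:

* **Detection filter.** A probe is dropped when its detection p-value
  exceeds `p_threshold` (default 0.01) in at least `sample_fraction`
  (default 50%) of samples. The rule is applied per cell — value above
  threshold, counted across samples. A per-probe *mean* detection p above
  threshold is a plausible alternative reading of common phrasing in the
  field; the per-cell rule is the one implemented, because it is
  well-defined for any missingness pattern and is what the failed-cell
  structure of the generator emulates.
* **SNP filter.** Probes flagged as overlapping known polymorphisms are
  removed, since genotype masquerades as methylation there.

The two filters commute (asserted by a test). Stratified quantile
normalisation is available (`quantile_normalize_stratified()`): classical
quantile normalisation — each sample's values replaced by mean order
statistics — applied within probe-design strata. It operates on beta-values
because raw intensities are out of scope; with simulated data already on a
common scale it is off by default in the pipeline.

# Per-CpG differential methylation

For each probe, ordinary least squares of the M-value on
$[1, \text{group}, \text{age}, \text{sex}, \text{BMI}]$, a two-sided t-test
on the group coefficient (patients minus controls) with $n-5$ residual
degrees of freedom, and Benjamini–Hochberg adjustment across all probes that
survived QC (never across the pre-filter set). A position is a DMP at
$q < 0.05$; its direction is hypo- or hypermethylated by the sign of the
adjusted M-scale coefficient, and its effect size is
$100 \times (\bar\beta_{\text{patients}} - \bar\beta_{\text{controls}})$
from unadjusted group means — a covariate-adjusted beta-scale coefficient
would no longer be a percentage-point methylation difference, so the
unadjusted means are deliberate.

Empirical-Bayes variance moderation (limma) is available behind
`moderate = TRUE` but off by default: with ~150 samples the per-probe
variance is well estimated and plain OLS keeps the inference assumptions
transparent. The two options agree closely on simulated cohorts (tested).

# Region annotation and gene aggregation

Gene-region categories follow the five-way manifest convention: promoter
(TSS200 ∪ TSS1500), 5'UTR, gene body, 3'UTR, intergenic (no gene link). A
probe overlapping several transcript regions is counted once in each
relevant category, so category counts may sum to more than the DMP total;
percentages always use the DMP total as denominator, and
intergenic + linked = total is an invariant. A differentially methylated
gene (DMG) is any gene with at least one DMP; genes are classed
hypo-only / hyper-only / mixed, a partition of the DMG set.

# Pathway over-representation and probe bias

Gene-level ORA is the one-sided upper-tail hypergeometric test of the
overlap between DMGs and each category, against the universe of genes with
at least one probe on the filtered array (not the genome). Genes carrying
many probes are more likely to harbour a DMP by chance; the probe-bias
variant therefore models category membership of *selected genes* (genes
with ≥ 1 selected probe) as a biased urn: Wallenius' noncentral
hypergeometric distribution with odds
$\omega = \overline{c}_{\text{in}} / \overline{c}_{\text{out}}$, the ratio
of mean probe counts inside and outside the category. The Wallenius mass is
computed from its integral representation with adaptive quadrature, which
is exact to quadrature precision; $\omega < 1$ is evaluated through the
complementary urn (swapping the roles of in- and out-of-category genes at
odds $1/\omega$) where the integrand is well behaved, and extreme odds
($\omega > 10^4$) return the limiting point mass at
$\min(n, K)$. Tests verify exact agreement with the central hypergeometric
at $\omega = 1$ over an exhaustive small grid, agreement with brute-force
enumeration of weighted draws on a six-gene case, and the deterministic
limit. BH adjustment is applied within each category collection
separately, mirroring per-database testing.

# Correlation enrichment (eQTM-style)

The headline procedure correlates every DMP's beta-values with every RNA's
normalised expression (Spearman, average ranks, computed as Pearson on
ranks in row blocks so memory stays bounded), then summarises each RNA
group by the proportion of pairs with $|\rho| > \tau$ (strictly greater;
default $\tau = 0.3$, the conventional "biologically relevant" cut).
Groups are compared two ways:

* **Pooled two-proportion Z-test** on the relevant-pair proportions,
  without continuity correction. Pairs are pooled as independent
  observations — deliberately, for fidelity to the standard procedure —
  although pairs sharing a DMP or an RNA are correlated. The practical
  consequence, which the package's own null simulations quantify, is that
  the test holds its nominal level when relevant pairs are rare and
  approximately independent, but becomes overdispersed when many relevant
  pairs share rows or columns. Interpret extreme z-statistics as effect
  summaries rather than calibrated tail probabilities.
* **Two-sample Kolmogorov–Smirnov test** on the full rho distributions,
  with the asymptotic tail
  $Q(\lambda) = 2\sum_{k\ge1}(-1)^{k-1}e^{-2k^2\lambda^2}$ at
  $\lambda = (\sqrt{n_e} + 0.12 + 0.11/\sqrt{n_e})\,D$,
  $n_e = n_a n_b/(n_a+n_b)$. The series is summed to convergence (it needs
  on the order of $1/\lambda$ terms when $\lambda$ is small, and
  $Q \to 1$ as $\lambda \to 0$).

P-values below double-precision epsilon are displayed as `< 2.2e-16` —
the floor R itself reports — while raw numbers are kept in machine-readable
output.

The comparison grid is DERNA vs non-DERNA, strength-associated vs
non-associated DERNAs, and the same strength split within each disturbed
pathway (mitochondrial, lipid, fibrosis). Whether correlations should use
patients only or the full cohort is not settled; the default uses the full
cohort (the heatmap convention spans all samples), and
`patients_only_correlations` flips it.

# Risk-factor screening

For each DMP, one joint multivariable OLS of the *beta-value* (not M — the
coefficients are then in methylation-proportion units per exposure unit) on
all candidate factors simultaneously, in patients only, since in-ICU
exposures are undefined for controls (a flag for the zero-coded alternative
is not provided; patients-only is the implemented reading). Significance is
raw $p < 0.05$ per association, with no multiplicity correction — a
deliberate fidelity choice for an exploratory screen, documented rather
than "fixed". A significant association is **harmful** when higher exposure
pushes methylation further from the control level (negative coefficient on
a hypomethylated DMP, positive on a hypermethylated one) and **protective**
in the opposite case; the rule is antisymmetric in the coefficient sign,
which the tests assert by negating exposure columns. Constant factors are
dropped with a warning, categorical factors are dummy-coded against the
first observed level, and remaining collinearity is an error naming the
columns.

# The synthetic cohort

`cohort_config()` defaults encode the emulated study conditions:
118 patients, 30 controls; planted absolute beta shifts averaging 0.026
with maximum 0.25, 63.6% of them hypomethylated; a ~2% DERNA fraction of
which 46.6% are strength-coupled; and a target coupling correlation of 0.5.
Probe and RNA counts default to 2000 each — a deliberate simulation scale
at which recovery statistics are estimable in seconds; the planted-DMP
fraction is likewise set to 5% rather than the sub-1% rate seen on full
arrays, so each cohort plants enough positions (~100) for sensitivity and
FDR estimates to have usable precision.

Generator mechanics, and the reasoning where the design was open:

* **Baselines.** Probe means are drawn from a bimodal mixture (40% near
  0.1, 40% near 0.9, 20% intermediate), the canonical shape of array beta
  distributions.
* **Noise.** No noise model is published for this design, so the per-cell
  noise is a free parameter: Gaussian on the M scale,
  `noise_sd_m = 0.5` by default, in the range of replicate variability
  typical for EPIC arrays. All recovery guarantees are stated under this
  default.
* **Planted effects.** Magnitudes are drawn from an exponential and mapped
  through $m = m_{\max}(u/u_{\max})^\gamma$ with $\gamma$ solved so the
  sample mean equals the target exactly; this pins both the mean (0.026)
  and maximum (0.25) of every draw rather than only in expectation. When
  too few positions are planted for both constraints to be satisfiable,
  the maximum is held and the rest spread evenly (or the mean alone is
  matched).
* **Covariate confounding.** Age, sex and BMI are drawn with overlapping
  patient/control distributions and leak into every probe with small
  random-signed coefficients, so unadjusted contrasts are biased and the
  covariate adjustment is actually exercised.
* **Coupling.** A coupled RNA is a monotone function of its linked probe's
  realised beta plus noise:
  $\text{expr} = \mu + s(a z + L g_c) + \tau\varepsilon$, where $z$ is the
  standardised probe beta, $g_c$ the centred group indicator, $L$ the
  planted log2 expression shift and $s = \pm1$ the coupling sign. The
  coefficient $a$ solves a quadratic so the Pearson correlation with $z$
  equals $2\sin(\pi\rho_S/6)$ — the normal-theory inverse of the target
  Spearman $\rho_S$ — given the empirically realised $\mathrm{cov}(g_c,z)$,
  while the group shift stays exactly $L$ and the non-group variance stays
  at the `expr_noise_sd` budget. Realised Spearman correlations land within
  about 0.03 of the 0.5 target on average.
* **Strength.** Strength-coupled DERNAs share a latent co-expression
  factor (loading 0.8 on their noise budget), representing a co-regulated
  pathway module, and the strength phenotype is a weighted sum of those
  RNAs' standardised expression plus noise, minus a patient deficit. The
  shared factor is not optional decoration: ~20 mutually independent RNAs
  cannot each correlate strongly with one composite (the squared
  correlations would have to sum past 1), so without co-expression no
  composite phenotype could be associated with most of the module.
* **Exposures.** Binary and duration exposures exist for patients only;
  each planted exposure effect acts on a subset of planted DMPs with sign
  aligned to the DMP's direction — i.e. harmful by construction — which is
  what the direction-classification recovery tests rely on.
* **Determinism.** One master seed expands into fixed per-stage child
  seeds, so identical configurations reproduce byte-identical cohorts and
  changing one stage's draws cannot silently shift another's.

## What the generator does and does not emulate

It reproduces bimodal betas, planted group shifts with realistic magnitude
structure, covariate confounding, detection failures, methylation-coupled
expression, a module-structured strength phenotype and directional exposure
effects. It does **not** emulate chip/batch effects, cell-type composition,
spatial probe correlation along the genome, count-based expression noise,
or raw-intensity artefacts. Passing recovery tests therefore demonstrates
that the estimators do what they claim under the stated noise model — not
that real cohort data meet these assumptions.

## Null-calibration note

Under a null cohort (no coupling, no expression shift) the DERNA/non-DERNA
z-test rejects at its nominal 5% level across seeds. Its p-value
distribution is nevertheless visibly discrete, because at $\tau = 0.3$ the
expected number of relevant pairs per group is of order one; the package's
acceptance tests therefore assert null uniformity as level calibration at
two thresholds rather than as a distributional goodness-of-fit, which the
discreteness would fail for reasons unrelated to exchangeability. At looser
thresholds the dependence between pooled pairs dominates instead and the
test is anticonservative — the caveat documented above.

# Numerical choices

* BH adjustment delegates to `stats::p.adjust` behind the `bh_adjust()`
  surface; an independent brute-force step-up implementation lives in the
  test suite as the oracle.
* Wallenius quadrature: `integrate` at `rel.tol = 1e-12`, tail normalised
  by the summed mass; complementary-urn swap for $\omega<1$; point-mass
  limit for $\omega > 10^4$.
* Spearman ties use average ranks; constant rows give `NA` correlations,
  excluded from numerator and denominator of every proportion with a
  logged tally.
* Degenerate pooled proportions in the Z-test (0 or 1) return
  $z = 0, p = 1$ and are flagged rather than producing 0/0.
* Zero coefficients at significance (a measure-zero event in continuous
  data) are excluded from harmful/protective classification and tallied.

# Problem sizes used by the validation suite

Unit tests run small cohorts (40/15 samples, 200–400 probes). The
recovery-property tests use the default 118/30-sample, 2000-probe,
2000-RNA cohort over 10–30 seeds: ≥ 80% sensitivity for planted
$|\Delta\beta| \ge 0.10$ at $q<0.05$, empirical FDR ≤ 0.075 at nominal
0.05, coupled-pair Spearman within ±0.1 of target, DERNA recovery ≥ 80%,
strength-module recovery ≥ 70%, and a decisive DERNA-vs-non-DERNA
proportion gap ($z_p < 10^{-6}$). These sizes were chosen so the whole
suite completes in about half a minute on one CPU while keeping Monte
Carlo error well inside the asserted margins.

# Known limitations

* Per-probe OLS assumes homoscedastic Gaussian M-value noise; no surrogate
  variables, cell-type deconvolution or DMR-level smoothing.
* The probe-bias odds $\omega$ uses the mean-probe-count ratio; other
  probe-bias estimators weight genes differently, and results can differ
  subtly for very skewed probe-count distributions.
* The pooled-pair Z-test inherits the dependence caveat above.
* The risk-factor screen is exploratory by design: raw $p<0.05$, joint
  linear adjustment only, no causal interpretation.
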