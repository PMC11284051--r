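# mrcascade

Integrative drug-target prioritization for case-control disease genetics,
combining single-cell differential expression, two-sample Mendelian
randomization (MR) over eQTL and pQTL instruments, Bayesian colocalization,
and a phenome-wide pleiotropy screen — the evidence cascade used to
nominate circulating proteins (e.g. FCRL3 in multiple sclerosis) as
therapeutic targets.

The package is for statistical geneticists and computational biologists who
want a tested, reproducible implementation of that cascade that can be
exercised end to end on synthetic data with known ground truth: every input
the pipeline consumes (LD-correlated genotype panels, QTL and case-control
GWAS summary statistics, negative-binomial single-cell counts with planted
cell types and DEGs, multi-trait association tables) can be generated by
seeded simulators bundled with the package.

## The statistics at the core

**Two-sample MR.** For instrument *j* with exposure effect β̂ₓⱼ (SE σₓⱼ) and
outcome effect β̂ᵧⱼ (SE σᵧⱼ):

- Wald ratio (single instrument): β̂ = β̂ᵧ/β̂ₓ, SE σᵧ/|β̂ₓ|.
- Fixed-effect IVW (≥ 2 instruments), with wⱼ = 1/σᵧⱼ²:
  β̂ = Σ wⱼ β̂ₓⱼ β̂ᵧⱼ / Σ wⱼ β̂ₓⱼ², SE = (Σ wⱼ β̂ₓⱼ²)^(−1/2) — the
  zero-intercept weighted regression of β̂ᵧ on β̂ₓ.
- Sensitivity analyses: MR-Egger (same regression with a free intercept;
  the intercept tests directional pleiotropy), the bootstrap-SE weighted
  median of per-instrument ratios, and Cochran's Q heterogeneity statistic.
- Reporting for a case-control outcome: OR = exp(β̂) with 95% CI
  exp(β̂ ± 1.96·SE).

**Colocalization.** Per-variant Wakefield approximate Bayes factors,
log ABF = ½[log(1 − r) + r·z²] with r = W/(W + σ²), accumulated in log
space under the five single-causal-variant hypotheses H0–H4 with priors
(p1, p2, p12) = (1e-4, 1e-4, 1e-5); a region "colocalizes" when PP4 > 0.8.

**Instruments.** Genome-wide-significant QTL variants (p < 5e-8), greedily
LD-clumped at r² < 0.001 (eQTL class) or r² < 0.01 (pQTL class) within
10,000 kb windows, then allele-harmonized against the outcome GWAS with
ambiguous palindromic variants removed.

**Single-cell stage.** QC (genes in ≥ 3 cells; cells with ≥ 250 detected
genes and mitochondrial fraction < 10%), log-normalization, PCA,
shared-nearest-neighbor Louvain clustering, marker-based cell-type
annotation, and per-cell-type Wilcoxon case-vs-control DEGs at
|log2FC| > 0.3, detection fraction > 0.25, BH-adjusted p ≤ 0.05.

A gene reaches the **top tier** of the final report iff its pQTL MR is
significant (p < 0.05) AND its cis region colocalizes with the disease
GWAS (PP4 > 0.8) AND its phenome-wide screen at p < 2e-8 is clean.

## Worked example

```r
library(mrcascade)

# simulate a valid-instrument study and estimate the causal effect
sim <- simulate_mr_instruments(20, causal_beta = 0.4,
                               exposure_n = 20000, outcome_n = 20000,
                               seed = 7)
fit <- run_mr(sim$instruments)
print(fit)
#> Two-sample MR (ivw), 20 instrument(s)
#>   beta = 0.409  se = 0.012  p = <2e-16
#>   OR = 1.51 (95% CI 1.47-1.54)
```

The IVW estimate recovers the planted causal effect of 0.4 (log-odds per
unit exposure) within sampling error; the OR is its exponential with a 95%
Wald interval. `summary(fit)` adds the MR-Egger and weighted-median rows
plus Cochran's Q and the Egger intercept test.

```r
# full synthetic cascade with the bundled configuration
cfg <- system.file("extdata", "demo_config.yaml", package = "mrcascade")
report <- run_pipeline(cfg, "demo_run")
report[, c("gene", "cell_type", "pqtl_or", "coloc_pp4", "phewas_verdict", "tier")]
#>    gene cell_type   pqtl_or    coloc_pp4 phewas_verdict         tier
#> 1 G0101    B_cell 0.5264578 1.000000e+00          clean          top
#> 2 G0103    T_cell 0.5176423 1.000000e+00        flagged fails_phewas
#> 3 G0102    B_cell 0.8122429 1.072491e-05          clean  fails_coloc
```

Three planted candidates survive to the protein stage: the true target
(shared causal variant, protective OR < 1, clean screen) is the sole
top-tier row; one decoy has distinct causal variants for protein and
disease and dies at colocalization; the other colocalizes but carries a
planted off-target association and is demoted by the phenome screen. All
intermediate tables, a run log of every filter decision, and a plain-text
summary are left in the output directory.

A thin command-line front end with one subcommand per stage
(`simulate`, `sc-deg`, `mr`, `coloc`, `phewas`, `report`, `run`) is
installed at `inst/cli/mrcascade.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","mrcascade.R",package="mrcascade"))')" \
  run --config inst/extdata/demo_config.yaml --out-dir demo_run
```

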