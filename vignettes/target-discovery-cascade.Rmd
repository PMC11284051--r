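---
title: "The target-discovery cascade: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The target-discovery cascade: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrcascade)
```

# Overview

`mrcascade` implements a five-stage evidence cascade for nominating drug
targets in a case-control disease: (1) case-vs-control differential
expression per cell type from single-cell RNA-seq; (2) selection of genetic
instruments from eQTL and pQTL summary statistics; (3) two-sample Mendelian
randomization of each candidate's expression/protein level against the
disease GWAS; (4) Bayesian colocalization of the protein signal with the
disease signal in the cis region; (5) a phenome-wide screen for off-target
pleiotropy. A candidate reaches the top tier only when the MR, coloc and
phenome gates all pass.

This vignette records the models behind each stage, the parameters that
matter (with defaults and units), the numerical choices, and the design
decisions that were genuinely open — together with what the synthetic-data
generators do and do not emulate.

# The synthetic-data generators

The generators exist so the whole cascade can be tested against known
ground truth without access to controlled human data.

**Genotypes and LD** (`simulate_ld_genotypes`). Each haplotype is a latent
AR(1) Gaussian process along a single synthetic chromosome (variants at a
fixed 1 kb spacing, 1-based positions), thresholded at the variant's minor
allele frequency; dosages are sums of two independent haplotypes. This is
the simplest mechanism that yields monotone, distance-decaying r² — the
property clumping and colocalization actually exercise. The `decay`
parameter is the adjacent-variant latent correlation (default 0.9; the
realized dosage correlation is attenuated by the dichotomization, e.g.
latent 0.9 gives adjacent dosage r of roughly 0.6). Allele pairs are drawn
from non-palindromic combinations so that harmonization never silently
discards a planted causal variant; palindromic handling is exercised by
hand-built fixtures instead.

**Two-trait summary statistics** (`simulate_two_trait_sumstats`). One
generating function per colocalization hypothesis H0–H4: H4 plants a single
shared causal variant, H3 two distinct ones, H1/H2 a variant in only one
trait, H0 none. The panel is split into disjoint halves so exposure and
outcome form a true two-sample design. Per-variant effects are marginal
single-variant regressions: ordinary least squares for the quantitative
exposure, and per-variant logistic regression for the case-control outcome,
so outcome betas are on the log-odds scale — the scale on which published
odds ratios for a disease GWAS live. The default case fraction is 0.4,
close to the roughly 41% case share of the large multiple-sclerosis GWAS
the cascade is modeled on.

**Instrument sets** (`simulate_mr_instruments`). Mutually independent
variants with true exposure effects drawn uniformly in magnitude from
0.1–0.3 (well away from zero, so weak-instrument dilution is negligible at
the default two-sample n = 20,000), observed with standard errors
1/sqrt(2f(1−f)n), and outcome effects `causal_beta` times the true exposure
effect plus optional pleiotropy plus noise. `pleiotropy_sd = 0` is the
valid-instrument regime used for coverage experiments;
`pleiotropy_mean > 0` produces directional pleiotropy that the Egger
intercept must detect.

**Single-cell counts** (`simulate_sc_counts`). Negative-binomial counts
(variance μ + φμ², default φ = 0.4) with: a shared baseline expression
profile; a per-type lognormal "expression program" (`type_profile_sd`,
default 0.6) that makes cell types separable the way real types are —
types differing only in a handful of marker genes are *not* recoverable by
unsupervised clustering, and early versions of the generator demonstrated
exactly that; marker genes boosted in their own type and suppressed
elsewhere; and planted case-vs-control DE genes shifted by a stated log2
fold change within their type. Planted DE genes also receive a moderate
baseline boost (`de_base_boost = 3`): the fold-change convention used for
calling (see below) adds 1 to the de-logged group means, which crushes
fold changes of lowly expressed genes, so a detectable plant must be
expressed at a realistic target-gene level. A configurable fraction of
cells is made genuinely low quality — under 250 detected genes or over 10%
mitochondrial counts — so QC has real work to do. Cells are split evenly
across conditions and across 5 donors per condition, mirroring a 5-vs-5
donor design.

What the generators do **not** emulate: realistic human LD maps and
population structure, donor-level expression variability and batch
effects, ambient RNA and doublets, winner's-curse selection in the QTL
panels, or sample overlap between exposure and outcome GWAS. Passing tests
on these simulations therefore demonstrates correctness of the estimators
and decision logic under their stated assumptions, not robustness to every
artifact of real data.

# Single-cell stage

QC defaults follow the standard workflow for PBMC-scale data: genes
detected in ≥ 3 cells; cells with ≥ 250 detected genes and mitochondrial
fraction < 10% (both "less than" rules are strict: a 249-gene cell is
removed, a 250-gene cell kept). The gene filter runs before the cell
filters; because removing cells can in turn push a gene below the 3-cell
floor, the pair is iterated to a fixed point, which also makes the filter
idempotent — a property the test suite asserts.

Normalization is `ln(1 + 1e4 · count / cell_total)`. Highly variable genes
(top 2,000 by standardized dispersion within mean bins) feed a PCA on
per-gene z-scores; the default of 31 components matches the component count
used in the workflow this package mirrors, but both numbers are
configuration values, not targets. Clustering is Louvain community
detection on a shared-nearest-neighbor (Jaccard-weighted, pruned at 1/15)
kNN graph in PC space — the standard method behind such workflows, chosen
here because the underlying study describes t-SNE only as visualization
and never names its clustering algorithm. The resolution knob
trades cluster granularity; annotation is robust to over-clustering because
each cluster is labeled independently by the marker set with the highest
mean z-scored expression (margin below `min_margin = 0.05` → "unassigned").

Differential expression uses the two-sided Wilcoxon rank-sum test per gene,
the default test of the cited workflow, with fold change computed as
`log2((mean(expm1 x) + 1 + 1e-9) / (mean(expm1 y) + 1 + 1e-9))` — the
pseudocount of 1 is the convention's, the 1e-9 guards exact zeros. Marker
discovery (one-vs-rest) uses inclusive thresholds |log2FC| ≥ 0.25 and
detection ≥ 0.25; case-control DEGs use strict thresholds |log2FC| > 0.3
and detection > 0.25 with BH-adjusted p ≤ 0.05, adjusted within each cell
type — each cell type is its own comparison family, so FDR is controlled
per family. A gene at |log2FC| = 0.29 is never a DEG, regardless of its
p-value.

# Instruments

Candidate instruments are variants with exposure p < 5e-8 (strict).
Clumping is the standard greedy scheme: take the lowest-p remaining
candidate as an index, discard candidates within ±10,000 kb whose r² with
it meets the threshold, repeat. Distinct defaults per instrument class —
r² < 0.001 for eQTL instruments, r² < 0.01 for the deliberately more
permissive pQTL panel — with the window interpreted as base-pair distance
≤ window_kb·1000 from the index, the usual clumping convention. Variants
absent from the LD reference are discarded (their independence cannot be
certified) and logged.

Harmonization aligns outcome records to the exposure's effect allele,
flipping the outcome beta and complementing its frequency when the allele
pair is swapped. Palindromic variants (A/T, C/G) with effect-allele
frequency inside (0.42, 0.58) — or missing — are strand-ambiguous and
excluded; 0.42 is the conventional ambiguity band. Harmonizing an already
harmonized set is a no-op. One unresolved ambiguity in the source
methodology is the pQTL significance threshold, described in one place as
genome-wide significance and in another as 0.05; both are exposed in the
configuration (`pqtl_p_threshold`, default 5e-8) rather than silently
resolved.

# MR estimators

The dispatch rule is fixed: one instrument → Wald ratio; two or more →
fixed-effect IVW; three or more additionally get MR-Egger, the weighted
median and Cochran's Q as sensitivity analyses (Q alone with exactly two).

Numerical choices:

- The Wald-ratio SE is first order (σᵧ/|β̂ₓ|), ignoring exposure-side
  uncertainty; the second-order delta SE is available behind a flag.
- IVW is fixed-effect by default (the residual scale pinned at 1); a
  multiplicative random-effects SE — inflation by max(1, sqrt(Q/(n−1))) —
  is available behind a flag and is reported alongside Q.
- Egger standard errors use the estimated residual scale floored at 1, so
  they never undercut the fixed-effect model; p-values are normal
  approximations.
- The weighted-median SE comes from a 1,000-draw parametric bootstrap with
  a fixed seed (instrument betas resampled at their stated SEs).
- Reported p-values are floored at 1e-300; display rounding to three
  decimals renders p < 0.0005 as 0.000, matching the convention of
  published MR tables.

The algebraic identity IVW ≡ precision-weighted mean of Wald ratios with
weights β̂ₓⱼ²/σᵧⱼ² is asserted to 1e-10 in the tests, as are closed-form
weighted-least-squares oracles for IVW, Egger and Q. Simulation checks:
the IVW mean over 500 valid-instrument datasets recovers a planted 0.4
within 0.02 with 95% CI coverage inside [92%, 98%], the Egger intercept is
inside ±2 SE in at least 93 of 100 null seeds, and Q p-values are uniform
under homogeneity.

# Colocalization

The module implements the standard single-causal-variant
approximate-Bayes-factor formulation — the computation performed by the
established colocalization package — with per-variant Wakefield log Bayes
factors `½(log(1−r) + r z²)`, `r = W/(W+σ²)`. Effect-prior SDs default to
W = 0.15² for quantitative traits and 0.2² (log-odds) for case-control
traits, the established defaults, both configurable. Priors default to
p1 = p2 = 1e-4 and p12 = 1e-5; only p12 is stated by the source analysis,
so the trait-specific priors keep the package defaults of the field.

All hypothesis sums are accumulated in log space with log-sum-exp; the H3
term is the log-difference `log(Σᵢ BF1ᵢ · Σⱼ BF2ⱼ − Σⱼ BF1ⱼBF2ⱼ)`,
computed stably and defined as exactly −∞ (PP3 = 0) for a single-variant
region, where no distinct-variant pair exists. Posteriors sum to 1 within
1e-9 for all inputs. Note that the posteriors are *not* invariant to
rescaling betas and SEs alone — the shrinkage factor r depends on σ
relative to the fixed prior SD; the exact invariance, asserted in the
tests, is to rescaling betas, SEs and prior SDs together.

The region is ±500 kb around the anchor (the exposure's index variant in
the pipeline), variants are harmonized before pairing, and the
colocalization decision is strictly PP4 > 0.8: the source describes the
rule both as "exceeds 0.8" and "≥ 0.8", so the strict reading is the
default and the boundary case (PP4 = 0.8 → no) is pinned by a test.

# Phenome-wide screen

The screen returns the target's associations with p strictly below 2e-8
(a record at exactly 2e-8 is excluded; the portal convention is not
documented, so strictness is a package decision, tested at the boundary).
The pleiotropy verdict is "clean" iff nothing significant remains after
excluding the study disease itself, identified by a case-insensitive
substring match on the trait name (`disease_trait`, default "multiple
sclerosis").

# Pipeline and the demo scenario

Candidate flow: DEG genes are intersected with genes that have an eQTL
panel; genes whose eQTL MR is significant (p < 0.05) proceed to the pQTL
stage (`require_eqtl_support`, default true — the narrative order of the
source analysis; set false to test proteins independently); proteins with
pQTL MR p < 0.05 go to colocalization and the phenome screen. The top tier
is exactly the conjunction of the three gates. Every stage writes its
table to the output directory and appends to a run log that cites the
stage, the threshold and the observed value for each decision, so every
row of the report is traceable. Re-running with the same configuration and
seed reproduces every output byte for byte.

The bundled demo plants three candidates, all with genuine DEG signal and
significant QTL instruments: a true target (shared causal variant in both
QTL classes, protective log-odds effect, clean screen), an H3 decoy whose
protein and disease signals come from two distinct variants 8 kb apart —
close enough (dosage r ≈ 0.6) that its MR looks nominally significant
through LD, which is precisely the confounding colocalization exists to
catch — and a phenome decoy that truly colocalizes but carries a planted
off-target association at 1e-9. Demo problem sizes (150 cells per type
across three types, 600 genes; 200-variant panels with 10,000 individuals
split into two samples of 5,000; 500 background phenome traits) are chosen
so the full cascade runs in seconds on a laptop while every gate still has
decisive power; the same sizes are used by the acceptance script.

# Known limitations

- Single-causal-variant colocalization only; allelic heterogeneity in a
  region (multiple causal variants per trait) violates its assumptions.
- No MR-PRESSO, multivariable MR or Steiger filtering; the sensitivity
  suite is Egger/weighted-median/Q.
- LD is consumed as a given correlation matrix; estimating it from
  reference panels, and proxy-variant lookup, are out of scope.
- The single-cell stage performs no batch correction or doublet detection,
  and the generator's donor structure is label-only (no donor random
  effects), so donor-level pseudoreplication is not modeled.
- The clumping and region logic assumes the single-chromosome coordinate
  layout of the interchange format; multi-chromosome inputs are handled
  per chromosome by the distance rule but have no special cis/trans logic.
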