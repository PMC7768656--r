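# GeneShapes

Distribution-shape classification of gene expression with shape-aware
survival stratification.

## The problem

In a cancer patient cohort, survival analyses built on gene expression
almost always assume every gene follows the same, symmetric distribution
across patients: the "interesting" patients are the ones in both extreme
tails. But cohort-scale expression is heterogeneous — some genes are
bimodal (distinct on/off transcriptional states), some are strongly
right-skewed, some are heavy-tailed — and a tails-versus-middle split is
the wrong patient grouping for those shapes. GeneShapes is for
statistically minded genomics analysts who want to (1) learn each gene's
distribution shape, (2) stratify patients accordingly, and (3) measure
whether that extra modeling effort actually buys predictive power.

## The method

Every gene is assigned one of seven labels by a bimodality-first pipeline:

1. Fit an equal-variance two-component Gaussian mixture
   `π·N(μ₂,σ) + (1−π)·N(μ₁,σ)` by EM and compute the Bimodality Index
   `BI = √(π(1−π))·|μ₂−μ₁|/σ`. If `BI > 1.1` the gene is **BIMODAL**
   and testing stops.
2. Otherwise test five unimodal candidates: Shapiro–Wilk on the data
   (**NORMAL**) and on its log (**LOGNORMAL**, positive genes only), and
   Lilliefors-style parametric-bootstrap Kolmogorov–Smirnov tests for
   **CAUCHY** (median/IQR fit), **GAMMA** (Newton MLE) and **PARETO**
   (closed-form MLE) — the bootstrap re-estimates parameters on every
   resample, and the p-value is `(1 + #{D_b ≥ D_obs})/(B + 1)`.
3. Candidates with `p > 0.01` compete; the largest p-value wins (ties:
   Normal, Lognormal, Cauchy, Gamma, Pareto). No winner ⇒ **UNKNOWN**.

The shape then drives survival analysis: symmetric genes split patients
at both tenth-percentile tails, skewed genes at the long tail only,
bimodal genes by mixture-mode membership; groups are compared by
log-rank test (α = 0.05) with Kaplan–Meier curves. A repeated 2/3–1/3
train/test protocol compares random-survival-forest classifiers built
from shape-aware, symmetric, and random gene selections by their
misclassification of good/poor survival on held-out patients.

## A worked example

Everything below is synthetic and seeded — no downloads. The `COMPARE`
preset generates a 500-gene, 300-patient cohort in which 20 bimodal
genes (upper mode at risk) and 10 right-skewed Gamma genes (long tail at
risk) carry a hazard ratio of 3, with 30% censoring:

```r
library(GeneShapes)
cfg <- shapeConfig(n_bootstrap = 99, n_trees = 200, n_repeats = 20,
                   n_selected_genes = 50, rng_seed = 11)
sim <- simulateCohort(benchmarkPanel("COMPARE", seed = 11))
calls <- classifyMatrix(sim$se, cfg)
calls
#> ShapeCalls with 500 gene(s)
#>   NORMAL        93 (18.6%)
#>   LOGNORMAL     75 (15.0%)
#>   CAUCHY        94 (18.8%)
#>   GAMMA         83 (16.6%)
#>   BIMODAL      153 (30.6%)
#>   UNKNOWN        2 (0.4%)
res <- runComparison(sim$se, cfg)
summarizeComparison(res)
#> Shape vs symmetric over 20 repeat(s)
#>   shape <= symmetric: 19 (0 tie(s), 1 loss(es))
#>   paired Wilcoxon p = 0.0001114
#>   mean rate RANDOM     0.5084
#>   mean rate SHAPE      0.4330
#>   mean rate SYMMETRIC  0.5184
```

Reading the output: classification recovers the simulated family mix
(the bimodal count includes strongly skewed genes absorbed by the
bimodality-first gate — see the vignette); in 19 of 20 paired
train/test repeats the shape-aware gene selection misclassifies fewer
held-out patients than the uniform symmetric assumption (43.3% vs
51.8% mean misclassification; the random arm sits at chance).

The per-gene prognostic scan and the auxiliary analyses follow the same
pattern:

```r
scan <- prognosticScan(sim$se, calls, cfg, assumption = "SHAPE")
head(scan[order(scan$p), c("gene_id", "family", "rule", "p")])
sweep <- boxCoxSweep(sim$se, lambdas = -10:10)
```

A command-line wrapper with `simulate` / `classify` / `survival` /
`compare` / `boxcox` / `purity` subcommands ships in
`inst/scripts/geneshapes.R`.

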