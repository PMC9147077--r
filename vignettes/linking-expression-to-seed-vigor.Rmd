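---
title: "Linking germination-phase transcript expression to soybean seed vigor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking germination-phase transcript expression to soybean seed vigor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vigorlink)
```

## The scientific problem

Seed *vigor* is the sum of the properties that determine how fast and how
robustly a seed lot germinates and establishes seedlings. Two lots can pass
the same germination test and still differ sharply in vigor, which is why
vigor is screened with a battery of auxiliary tests: germination speed
(t50), seedling length and dry mass, emergence, survival after accelerated
aging, electrolyte leakage (electrical conductivity), and lipid
peroxidation (malondialdehyde, MDA).

During germination *sensu stricto* — the first hours of imbibition, before
radicle protrusion — the embryonic axis switches on DNA-repair and
cell-wall-remodeling programs. `vigorlink` implements a statistical chain
for asking whether the expression of a panel of such growth-related genes,
measured by qPCR in the imbibing embryonic axis, is associated with
lot-level vigor:

1. **Relative quantification.** Cq tables are converted to fold changes by
   the 2^−ΔΔCt method against a dry-seed control group, with two (or more)
   reference genes combined by the arithmetic mean of their Cq.
   Significance of per-gene ratios uses a pair-wise fixed-reallocation
   randomization test.
2. **Vigor phenotyping.** Cumulative germination curves are fitted with a
   Hill function to extract t50; biochemical assays are reduced to
   lot-level trait values; groups are compared by one-way ANOVA with
   Tukey HSD compact letters.
3. **Co-expression structure.** A Spearman correlation matrix over genes,
   thresholded at r > 0.70 (p ≤ 0.05) for display, and a hierarchical
   clustering of the genes-as-variables under a first-principal-component
   homogeneity criterion, cut into k = 5 groups.
4. **Association.** For each gene cluster, 10,000 bootstrap resamples of
   the aligned (expression, trait) sample rows; each resample is scored by
   the first canonical correlation of a regularized canonical correlation
   analysis (RCCA); clusters are ranked by the mean of their bootstrap
   distributions with Tukey letters.

Because no study dataset is distributed with the package, a synthetic-data
module generates inputs with the full design — two cultivars × two lots ×
three imbibition timepoints (0, 6, 10 h) × three biological replicates, 20
target and 2 reference genes — and a *known* planted association, so the
whole chain can be exercised and its recovery properties measured.

## Models and their assumptions

### Relative quantification

With amplification efficiency fixed at 2 (the 2^−ΔΔCt premise; no
efficiency correction is attempted), for target gene *g* in sample *s*:

ΔCt(g, s) = Cq(g, s) − mean of the sample's reference Cq;
ΔΔCt = ΔCt(g, s) − mean ΔCt over control replicates; RQ = 2^−ΔΔCt.

The control group is the dry seeds (0 h) of **lot 1** of the same cultivar.
Whether the second lot's dry seeds should instead be normalized to their
own lot is ambiguous in practice; both conventions are implemented
(`control = "lot1"` vs `"own_lot"`), with lot 1 the default. Averaging
reference genes on the Cq scale equals a geometric mean of linear
quantities, the standard choice for multi-reference normalization. Missing
Cq values propagate to `NA` cells and are excluded pairwise downstream,
never imputed.

The randomization test reallocates replicate (target Cq, reference Cq)
pairs between the two groups as units and uses the absolute log2 ratio as
its statistic. With few replicates the reallocations are enumerated
exhaustively and the exact tail proportion returned; otherwise `n_perm`
(default 2000) random reallocations give `p = (1 + k)/(1 + n_perm)`.

### Germination kinetics

Cumulative germination percentage is modeled as a Hill curve
`G(t) = Gmax · t^h / (t50^h + t^h)`, so `G(t50) = Gmax/2` exactly by
parameterization, and t50 is "time to 50% of the fitted maximum" (not of
the seeds sown — the distinction matters when Gmax < 100). Fitting is
Levenberg–Marquardt least squares with multi-start in the Hill exponent
(h ∈ {1, 4, 10}) and a t50 start from linear interpolation at
half-maximum; if no start converges the interpolated t50 is returned,
flagged. Observations scored every 6 h are interval-censored; the fit
treats the recorded times as exact — a documented simplification that
biases t50 by at most half the scoring interval.

### Variable clustering

For a cluster *C* of quantitative variables, homogeneity
`H(C) = Σ_j r²(x_j, y_C)` with `y_C` the cluster's first principal
component, which for standardized variables equals the largest eigenvalue
of the cluster's correlation matrix (the package asserts this equivalence
against an independent principal-component computation). Merging proceeds
greedily on the loss `d(A, B) = H(A) + H(B) − H(A ∪ B) ≥ 0`; ties are
broken by lexicographic gene order so results do not depend on column
order. Only the quantitative branch is implemented — every expression
variable is quantitative here. The default cut is k = 5; since no
principled rule fixed that number, `suggestK()` offers a secondary
largest-relative-jump heuristic, clearly subordinate to the user's choice.

### Regularized canonical correlation

Canonical correlations are the square roots of the eigenvalues of
`(Cxx + λx I)⁻¹ Cxy (Cyy + λy I)⁻¹ Cyx`. The ridge constants keep the
within-block covariances invertible when variables approach or exceed the
sample count — exactly the regime here (20 genes, 13 traits, 24 aligned
samples; and the trait block has only 4 distinct rows, so `Cyy` is rank
deficient by construction). Columns are standardized before penalization
by default so that one λ is comparable across blocks; a
`standardize = FALSE` switch penalizes raw covariances for compatibility
with implementations that do so. Defaults are λx = λy = 0.1 — small,
symmetric, and sufficient to stabilize p ≈ n blocks — and
`chooseLambda()` offers leave-one-out cross-validation of the first
canonical correlation over a grid when a data-driven choice is preferred.
The reported "first eigenvalue" is the first canonical correlation ρ₁ (a
correlation, matching how the bound "mean correlation > 0.7" reads); a
`squared` switch in `bootstrapRho1()` records ρ₁² instead.

### Bootstrap association and ranking

Expression samples at 6 h and 10 h are pooled; each sample row of the
gene block is paired with its lot's row of the trait matrix (lot-level
traits broadcast to replicate-level expression — vigor is a lot property;
a replicate-pairing mode matches trait replicate *i* to expression
replicate *i* instead). Resampling draws aligned rows jointly with
replacement, preserving the X–Y coupling that is the estimand; resampling
either block alone would destroy it. Degenerate resamples (any constant
column) are redrawn and counted, so every group's distribution holds
exactly B values and groups are comparable. Ranking pools the per-group
bootstrap vectors into a one-way ANOVA with Tukey letters. **Caveat,
recorded in the output metadata too:** treating bootstrap resamples as
independent observations makes those letters descriptive, not inferential
— with B = 10,000 "replicates", minuscule differences in mean become
"significant". The scientific conclusion should rest on the ranking and
the separation of the distributions, not on the letters alone.

## What the synthetic data emulate — and what they do not

The generators plant the structure the analysis assumes:

- a latent vigor value `v` fixed per (cultivar, lot) — vigor is measured
  at lot level — defaulting to `+1, −0.5` (cultivar 1, lots 1–2) and
  `+0.5, −1` (cultivar 2), mirroring a design where lot 1 outperforms
  lot 2 and cultivar 1 outperforms cultivar 2;
- a planted set of 6 of the 20 target genes whose log2 expression at 6 h
  and 10 h (never in the dry seed, the shared control baseline) rises by
  `loading · v` cycles, with loading 0.9 by default;
- co-expression blocks (the planted set plus four blocks of the remaining
  14 genes) sharing per-sample latent factors (sd 0.5 log2 units), so the
  variable clustering has a recoverable 5-group truth;
- a shared, vigor-independent imbibition up-regulation trend (≈1–1.5 log2
  units, jittered per gene), emulating the broadly induced growth program;
- Gaussian Cq noise (sd 0.25 cycles) on the log scale; trait values
  `mean + magnitude·(sign·v + N(0, 0.3))` with conductivity and MDA
  signed negative; germination times drawn per seed from a Hill
  distribution whose true t50 is `base(condition) · exp(−0.15 v)`, scored
  every 6 h on 25 seeds per replicate (binomial counting noise);
- trait replicates default to n = 8, germination to 4 replicates —
  the replicate counts typical of these assays.

Not simulated: plate effects, primer efficiencies ≠ 2, inter-gene
efficiency differences, spatial field variation, or seed-to-seed
covariance beyond the lot factor. Passing recovery tests on these data
therefore shows the chain is *correct and well-calibrated under its own
assumptions*; it does not certify performance on real qPCR data with
plate structure or efficiency drift.

## Numerical choices

- Hill fits bound Gmax ∈ (0, 100], t50 > 0, h > 0; the best converged
  multi-start by RSS wins.
- Merge losses are clipped at 0 and asserted ≥ −1e−9; homogeneity uses a
  symmetric eigensolver.
- Canonical correlations are clipped to [0, 1]; the RCCA core uses
  Cholesky whitening and an SVD, and at λ = 0 agrees with classical CCA
  to 1e−8 (tested against an independent SVD oracle).
- Exhaustive randomization enumerates when C(n, n1) ≤ n_perm; the tail
  comparison uses a 1e−12 tolerance so exact ties count as extreme.
- Spearman p-values use the t approximation with pairwise-complete n.
- All CSV writers emit 17 significant digits so write/read round-trips
  are bit-exact.

## Problem sizes used in the checks

The packaged checks run the full chain at the study's own scale (24
aligned samples, 20 genes, 13 traits). Bootstrap distributions use
B = 10,000 for the headline per-timepoint bound and B = 2,000 per group
for the 20-seed recovery study; t50 recovery uses 25-seed binomial
courses, and the null calibration of the randomization test uses 200
lot-vs-lot comparisons under a zero-loading configuration. Those sizes
make every distributional claim in the test suite a direct computation,
not an extrapolation.

## Known limitations

- The Tukey-letter caveat above: letters over bootstrap replicates are
  descriptive.
- The 2^−ΔΔCt model assumes perfect doubling per cycle; genes with poor
  efficiency will be mis-scaled.
- Broadcasting lot-level traits to expression replicates makes the
  effective trait sample size 4, not 24; the ridge and the bootstrap make
  the estimate stable, but the trait block cannot support more than a few
  canonical dimensions.
- With n = 12 samples per timepoint and 20 genes, the per-timepoint RCCA
  is overparameterized; the per-timepoint means should be read as the
  consistency check they are, not as unbiased effect sizes.

## A worked run

```{r pipeline, eval = FALSE}
res <- runPipeline(list(simulate = list(), B = 2000, seed = 1))
res$consistency$means   # per-timepoint mean bootstrap rho1
rankingTable(res$ranking)
res$ranking@top_genes   # the recovered planted set: G01..G06
```
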