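---
title: "Reconstructing liver zonation from spatial transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing liver zonation from spatial transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zonatlas)
```

## The scientific problem

The liver lobule is a roughly hexagonal unit in which blood flows from the
portal nodes at the corners to the central vein. Hepatocytes divide labor
along this portal–central (PN–CV) axis: gluconeogenesis and albumin
production sit periportally, xenobiotic metabolism and glutamine synthesis
pericentrally. A 10x Visium slide samples the lobule as ~55 µm spots, each a
small neighborhood of cells at some radial position, but the spots carry no
annotation of where on the PN–CV axis they sit. zonatlas reconstructs that
coordinate from expression alone, classifies each gene's spatial pattern
along it, and asks how the patterns move between nutritional states
(control, fasted, refed).

## The pipeline, step by step

**QC and normalization.** Per spot we record detected genes, total UMIs, and
the UMI fractions of mitochondrial (`mt-*`) and hemoglobin genes. Counts are
normalized as `log(1 + count * scale / spot_total)` with `scale = 1e4`. This
log library-size normalization is deliberately simple and fully specified; it
replaces regression-based variance stabilization, which is an external
method with its own fitted parameters. On overdispersed counts it leaves
more mean–variance trend than a variance-stabilizing transform would, which
is one reason downstream fits operate on binned means (below).

**Clustering.** The top 2000 genes by variance are standardized and reduced
to 30 principal components; spots are connected in a shared-nearest-neighbor
graph (k = 15, Jaccard edge weights, pruned at 1/15) and partitioned by
Leiden modularity optimization at resolution 0.8 — the construction popular
single-cell toolkits use. Clusters whose median hemoglobin fraction exceeds
0.1 are flagged *minor*: such globin-rich spots reflect red-blood-cell
contamination near vessels, not hepatocytes, and are excluded from axis
inference. The exact number of clusters is data-dependent and is not a
quantity we interpret.

**Diffusion pseudotime.** On the major spots we build a Gaussian kernel on
Euclidean distances in PC space with a per-spot adaptive bandwidth (the
distance to the k-th neighbor), row-normalize it into a transition matrix
and take its leading non-trivial eigenvectors scaled by their eigenvalues.
Pseudotime is the distance, in that diffusion space, from the medoid of a
root cluster (by default the cluster with the highest mean portal-marker
expression), min–max rescaled to [0, 1]. The default uses a single
diffusion component: a lobule's zonation axis is one-dimensional, and we
found the higher components mostly encode between-sample variation and
embedding curvature, both of which distort root distances. The axis is then
*oriented* with landmark genes (Alb, Cyp2f2 portal; Glul, Lgr5 central): if
portal markers correlate positively with t, the axis is flipped, so t = 0
is always periportal. Two numerical details matter. The adaptive bandwidth
uses the k-th smallest distance above a relative tolerance (1e-8 of the
largest distance) so that duplicated spots — which genuinely occur in
noise-free data — cannot collapse the kernel. And connectivity is checked
on the k-NN graph of unique coordinates; a disconnected graph is an error
asking for a larger k rather than a silently broken ordering.

**Zonation classification.** Genes detected with more than 10 counts in at
least 200 spots are analyzed. For each gene and condition, expression is
summarized as mean normalized expression in 20 equal-width pseudotime bins,
and three models are fitted by least squares:

* quadratic polynomial `a + b t + c t²` (monotone or gently curved change);
* Gaussian peak `h exp(−(t − μ)² / 2σ²)` (localized maximum);
* inverted Gaussian `C − h exp(−(t − μ)² / 2σ²)` (interior trough).

The polynomial optimum is computed exactly (the model is linear in its
parameters — identical to iterating Levenberg–Marquardt from unit starting
values). The Gaussian families are fitted with Levenberg–Marquardt from the
conventional starts (peak height 1, mean at the average pseudotime, sd 1;
the inverted Gaussian's constant at the maximum observed expression). Two
fitting choices deserve explanation:

* *Weighted least squares.* Bin means enter with weights equal to the number
  of spots per bin; the variance of a bin mean scales as 1/n, so this is
  equivalent to fitting every spot at its bin center. Without weights,
  sparse bins near the lobule center (few spots at small radii) dominate the
  tails of the fit. Bins resting on fewer than 5 spots are treated as
  missing, like empty bins.
* *A second, data-driven start.* At σ = 1 over a unit pseudotime range the
  Gaussian is nearly constant, so the residual surface is insensitive to μ
  and the fit can terminate in a degenerate optimum (μ at a bound) for
  narrow features. Each Gaussian family is therefore also started from the
  observed extremum location with width a quarter of the range, and the
  lower-RSS solution wins. Parameters are mildly bounded (h, C ≥ 0,
  μ ∈ [−0.5, 1.5], σ ≤ 10, and σ at least the spacing of the fitted t
  values — a narrower feature is unidentifiable from binned data and
  produces "needle" fits that slip between bin centers).

The best model is chosen by AIC, `n log(RSS/n) + 2k` with k = 3, 3, 4
parameters, ties broken polynomial → Gaussian → inverted Gaussian. Zonation
strength is the **normalized range**: (max − min)/max of the fitted curve
over a 512-point grid spanning the observed pseudotime range. Genes below
0.1 are **non-zonated**. Otherwise, with t oriented PN→CV: an inverted
Gaussian with an interior trough and both endpoints at least
0.1 × max above it is **bipolar**; else the argmax location decides —
≤ 0.25 **periportal**, ≥ 0.75 **pericentral**, interior **midzonal**. The
0.25/0.75 pole boundaries and the AIC selection are package choices (they
are exposed in the configuration); the 0.1 cutoff and the three model
families with their starting values are the published procedure. Ranges at
relative machine precision are reported as exactly 0, so constant profiles
are non-zonated by construction.

**Transitions, differential expression, pathway scores.** Labels from two
conditions are cross-tabulated over shared genes into a 5×5 transition
table whose marginals conserve gene counts exactly (per-cell gene lists are
kept for Sankey export). Differential expression between spot groups uses
the two-sided Wilcoxon rank-sum test (exact enumeration when both groups
have ≤ 10 tie-free values, tie-corrected normal approximation otherwise),
an average log2 fold change `log2((mean_a + 1)/(mean_b + 1))` on de-logged
normalized values, and Benjamini–Hochberg FDR; the default calling
thresholds are |log2FC| > 0.25 and FDR < 0.05. Per-spot pathway activity
uses the ssGSEA construction: genes ranked by expression within a spot, a
running sum of the difference between the rank-power-weighted in-set ECDF
(exponent α = 0.25) and the unweighted out-of-set ECDF, integrated over all
positions. The five MSigDB pathway names used for liver nutrient signaling
ship as an empty registry — memberships are MSigDB content and must be
supplied as a GMT file.

## What the simulator emulates — and what it does not

The generator lays out hexagonal lobules (inradius 0.25 mm, i.e. ~0.5 mm
diameter) on a triangular Visium-like lattice, about 500 spots per lobule,
spanning 10–13 concentric spot layers to mirror the ~9–12 cell layers of a
mouse lobule. Each spot's truth is its radial coordinate r (0 = central
vein); the analysis axis truth is t = 1 − r. Genes come from five families
matching the classifier's label set, 120 each by default:
periportal/pericentral monotone quadratics (fold change ≥ ~2.5 between
poles), midzonal Gaussian peaks (μ_r ∈ [0.35, 0.65], σ ∈ [0.08, 0.15]),
bipolar inverted Gaussians, and flat genes. Counts are negative binomial
(single global dispersion, default size 10) around expected proportions,
with log-normal library sizes around 24 000 UMIs per spot — the depth scale
of mouse-liver Visium data, at which the count > 10 detection filter is
meaningful for a 600-gene panel.

Three structural choices are worth knowing:

* **Compositional balance.** Each pericentral gene is the exact mirror of a
  periportal draw, and each bipolar gene is the complement of a midzonal
  draw under a constant; pairs share abundance weights and condition
  effects. The summed expected expression is therefore near-uniform in r
  (within ~1%), so per-spot proportion normalization does not paint
  spurious zonation onto flat genes. Real tissue is not perfectly balanced;
  on real data, compositional effects are a genuine confounder that this
  simulation deliberately factors out so that classifier errors can be
  attributed to the classifier.
* **Condition effects.** 10% of each zonated family switches to a flat
  profile in the refed state (level matched to the original profile's mean
  — the lipogenic-gene behavior of Fasn/Thrsp), and a further 10% gets a
  1.5× amplitude scaling when fasted. Mitochondrial genes are boosted 1.5×
  in the fasted sample; 5% of spots are erythroid-contaminated with
  hemoglobin proportions inflated 20-fold.
* **What is missing.** No batch or slide effects (integration is out of
  scope), no per-gene dispersion, no spatial covariance beyond the radial
  profiles, no cell-type mixtures, and the noise model is not calibrated to
  any deposited dataset. Passing recovery tests here shows the pipeline's
  inference is correct under its own generative assumptions — not that real
  tissue satisfies those assumptions.

A note on erythroid spots: at the simulated 20-fold inflation, erythroid
spots carry ~20% hemoglobin UMIs, and graph clustering isolates the
majority — but not all — of them (randomly placed contaminated spots keep
most of their hepatocyte expression, so some remain embedded in
hepatocyte-dominated neighborhoods). The flagging rule itself (median
hemoglobin fraction > 0.1 → minor) is exact given a grouping.

## Problem sizes and determinism

The default study is 2 lobules × 500 spots per condition × 3 conditions
(~3 450 spots) and 600 genes; the full pipeline runs in about a minute on
one core, and the recovery checks in the test suite reuse a single shared
run. Every stochastic stage consumes a seed derived from the one global
seed by a fixed stage-name hash, so a configuration and seed determine
every artifact bit-for-bit. At the default settings the pipeline recovers
the programmed truth with macro-averaged label accuracy above 0.9 across
seeds, non-zonated recall near 1, and Spearman correlation above 0.9
between inferred and true axis positions — these same quantities are
recomputed by `scripts/acceptance.R` and asserted by the test suite.

## Known limitations

* The axis is assumed unbranched; tissues with genuine branching topology
  need a trajectory method, not a diffusion coordinate.
* Classification operates on binned profiles; extremely narrow features
  (under one bin width) are deliberately unidentifiable.
* The Wilcoxon/BH differential expression path treats spots as independent
  replicates, as the original marker-gene analyses do; it is a screening
  tool, not a hierarchical model over animals.
* With only a single sample per condition, condition effects are
  confounded with sample effects by design; the merge step does not attempt
  integration.
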