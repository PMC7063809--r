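---
title: "Weighted co-expression network analysis with wgcnet: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted co-expression network analysis with wgcnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgcnet)
```

# Scope

`wgcnet` builds weighted gene co-expression networks from a gene-by-sample
expression matrix and relates network modules to clinical traits. It covers
the full chain used in small-cohort transcriptomic studies: transcript-to-gene
collapsing, top-expression filtering, covariate and principal-component
confounder screens, unsigned soft-power adjacency, topological overlap,
module detection by average-linkage clustering with an adaptive tree cut and
eigengene-based merging, module-trait correlation with covariate
residualization and Benjamini-Hochberg false discovery rate control, and
quantile-threshold hub-gene identification. A factor-model simulator with
planted modules, trait effects and sex/race confounding provides ground truth
for validation.

# The network model

## From expression to adjacency

For genes $i, j$ with profiles $x_i, x_j$ across $n$ samples, the base
similarity is the Pearson correlation $r_{ij}$. The *unsigned* adjacency
raises its magnitude to a soft-threshold power $\beta$:

$$a_{ij} = |r_{ij}|^\beta .$$

The power suppresses weak correlations smoothly instead of imposing a hard
cutoff; the unsigned form treats strongly anti-correlated genes as connected,
which matches a module model in which genes may load on a shared latent
factor with either sign. `adjacency()` implements this; the default
$\beta = 7$ reproduces the parameterization of the adipose-tissue cohort
analysis this package's defaults mirror.

## Choosing the power

`pick_soft_threshold()` evaluates candidate powers by the scale-free
topology criterion: connectivity $k_i = \sum_{j \ne i} a_{ij}$ is binned
into 10 equal-width bins and $\log_{10} p(k)$ is regressed on
$\log_{10} \bar k$ over non-empty bins. The chosen power is the smallest
whose fit reaches $R^2 \ge 0.8$ with a negative slope; when no candidate
qualifies the best-fitting power is used and a warning raised. Binning and
unweighted least squares are deliberate simple choices: the criterion is a
heuristic, not an estimator, and finer binning schemes change the chosen
power by at most one in our simulations. Both the plain $R^2$ and the slope
are reported so users preferring the signed convention
($-\operatorname{sign}(\text{slope}) \cdot R^2$) can read it off directly.

## Topological overlap

Direct adjacency is noisy at small $n$; the topological overlap matrix (TOM)
stabilizes it by crediting shared neighbourhoods:

$$\mathrm{TOM}_{ij} =
  \frac{\ell_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}}, \qquad
  \ell_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj},$$

with $\mathrm{TOM}_{ii} = 1$. `topological_overlap()` computes $\ell$ as a
single dense matrix product (the zero diagonal removes the $u = i, j$
terms), guards the impossible zero denominator with the limiting value 1,
and clips floating-point excursions into $[0, 1]$. The whole 5,758-gene
matrix used in the reference analysis fits comfortably in memory as a dense
double matrix, so no blockwise processing is used; module boundaries can
therefore differ slightly from tools that split large gene sets into blocks.

One behaviour of the min-normalized TOM is worth knowing: a gene with few
connections, all of which point into one tight module, can have
near-maximal overlap with that module even if its individual correlations
are modest, because the denominator is governed by its own small $k$. At
small sample sizes this makes chance-correlated background genes look like
genuine peripheral members. This is a property of the statistic, not of the
implementation, and it bounds what any TOM-based pipeline can resolve at
$n \approx 26$ (see *Validation* below).

# Module detection

`detect_modules()` chains four steps: TOM dissimilarity $d = 1 -
\mathrm{TOM}$, average-linkage hierarchical clustering
(`stats::hclust`), the adaptive cut `cut_tree_dynamic()`, and eigengene
merging `merge_close_modules()`.

## The adaptive tree cut

The cut variant is the package's own design (the reference analysis names
only its minimum module size and merge height, not the cut algorithm), in
the dynamic hybrid family: tree-based branch decomposition followed by a
PAM-like assignment stage.

1. **Adaptive ceiling.** Branches are considered only below
   `cut_height_frac` (default 0.995) times the maximum joining height. On
   TOM dendrograms the merges among unconnected background genes crowd
   directly beneath the maximum, so this data-driven ceiling strips loose
   genes without a fixed absolute threshold.
2. **Branch decomposition.** Each branch under the ceiling is split
   top-down wherever both sub-branches hold at least `min_module_size`
   (default 10) leaves; smaller side-branches are peeled into an unassigned
   pool. The decomposition intentionally over-splits — fragments of one
   true module are reunited later by the eigengene merge, whose fragments
   correlate almost perfectly.
3. **Cohesion backstop.** A candidate branch survives only if its mean
   internal overlap is at least `tightness` (default 2) times the overlap
   implied by the ceiling height, dissolving the occasional chance
   agglomerate that forms just under the ceiling.
4. **Iterated PAM-like assignment.** Every gene is then (re)assigned to the
   cluster with the highest mean overlap to it *relative to that cluster's
   own internal cohesion*, provided the ratio reaches `pam_cohesion`
   (default 0.35); otherwise it is unassigned (grey). Cohesions are
   refreshed and the assignment iterated (3 rounds), in the manner of
   partitioning around medoids. The self-normalization matters: it makes
   membership judgements comparable between tight and loose modules.

The defaults for the ceiling, backstop and cohesion ratio were calibrated
on the package's own simulator (planted factor modules over pure-noise
background across a range of strengths and seeds) by maximizing adjusted
Rand index against planted labels; they are reported here as the package's
defaults, and all are exposed as arguments. A plain static cut
(`cut_tree_static()`) is available as a fallback.

## Merging and labeling

`merge_close_modules()` computes one eigengene per module, clusters
eigengenes by $1 - r$ (average linkage), fuses every group joined below
`merge_cut_height` (default 0.25, i.e. eigengene correlation above 0.75),
recomputes, and repeats until no pair remains below the threshold — so
chained merges (A close to B, B close to C) resolve in one pass structure.
Modules are then renumbered by decreasing size and colored with the
conventional palette (turquoise, blue, brown, ..., magenta 9th, ...,
darkgreen 22nd); label 0 is always grey. The post-hoc significance-based
module reassignment stage found in some pipelines is not implemented: with
its threshold set to zero — the reference parameterization — it can never
move a gene, so disabling it entirely is the faithful reading.

# Eigengenes and trait association

The module eigengene is the first principal component of the module's
gene-standardized submatrix across samples, unit-norm and zero-mean, with
its sign fixed so the mean correlation with member genes is positive.
`module_membership()` (kME) and `gene_significance()` (absolute
gene-trait correlation) follow the usual definitions.

`module_trait_correlation()` first residualizes each trait on its declared
adjustment covariates by ordinary least squares (`adjust_trait()`); the
default metadata rule adjusts body-size traits (height, weight, BMI, fat
measures) for sex and race at baseline and for sex at the later follow-up
timepoints, mirroring the covariate screen outcome of the reference cohort.
Only the trait is residualized, not the eigengene, and the correlation test
keeps $n - 2$ degrees of freedom: the procedure implements *adjusted
traits*, not a formal partial correlation (at $n = 26$ the difference in
$p$ is negligible relative to sampling noise). Two-sided $p$-values come
from $t = r\sqrt{(n-2)/(1-r^2)}$, and Benjamini-Hochberg adjustment is
applied across the whole module-by-trait family by default
(`fdr_scope = "per_trait"` is available; the matrix-wide family matches how
joint module-trait heatmaps are usually thresholded). Significance is
declared at adjusted $p < 0.05$.

The screens are standard: `screen_covariate_associations()` fits simple
linear regression (quantitative predictors) or one-way ANOVA (categorical)
per outcome-predictor pair and reports raw $p$ — multiplicity adjustment is
deliberately omitted there because the screen is descriptive.
`pc_confounder_screen()` tests each variable against the first three
principal components of the standardized expression matrix (per-PC tests,
regression or ANOVA by kind) and BH-adjusts across the entire
variable-by-component family. Ages can be screened both continuously and
dichotomized at 50, matching the convention of comparing age on the same
footing as binary sex and race. Testing per component rather than jointly
was the other open choice; per-PC tests report which component carries an
association, which is the actionable information in a confounder screen.

# Hub genes

The hub procedure is the thresholded-connectivity variant:
`tom_quantile_cutoff()` takes the empirical 95% quantile (linear
interpolation) of the upper-triangle off-diagonal TOM entries — the
diagonal is excluded so its 1's cannot inflate the threshold — and two
genes count as connected when their overlap strictly exceeds it.
`intramodular_connectivity()` counts connections within the same non-grey
module only, and `identify_hubs()` flags the top
$\lceil 0.10 \times \text{module size} \rceil$ genes per module (ties
broken by gene ID and flagged), so every module of at least the minimum
size contributes at least one hub. Ranking is per module by default; a
pooled ranking across candidate modules is available behind a flag.
kME-based hub definitions are intentionally out of scope — hubs here are
defined by thresholded TOM connectivity.

# The simulator

`generate_dataset()` draws, for each planted module $m$, a latent
per-sample factor $f_m \sim N(0, 1)$ and generates member genes as

$$x_g = \lambda_m f_m + \sqrt{1 - \lambda_m^2}\, \varepsilon_g,
  \qquad \lambda_m = \sqrt{\texttt{within\_module\_cor}_m},$$

with unit-normal noise, so the expected within-module correlation is
exactly `within_module_cor` (and the noiseless limit is
`within_module_cor = 1`). Background genes are pure noise. Traits are
linear combinations of module factors plus additive sex/race effects plus
Gaussian noise; sex and race are Bernoulli(15/26), the composition of the
26-patient cohort the defaults emulate. Options plant negative loadings on
half of a module's genes (exercising unsigned adjacency) and elevated
loadings on designated genes (planting connectivity hubs).

The simulator emulates block-correlated modules with exchangeable loadings
and independent factors. It does not emulate probe-level noise, batch
effects, correlated module factors, heavy-tailed expression, or missing
values. Passing tests on this generator therefore demonstrates correctness
of the algorithms under the factor model, not robustness to microarray
artifacts — for deposited data the usual platform QC still applies
upstream.

# Validation results and statistical limits

The test suite checks every stage against independent oracles (triple-loop
TOM, definitional step-up FDR, naive $O(n^3)$ average linkage, enumerated
connectivity counts) and against planted ground truth. Two findings shape
how the recovery results should be read:

* At the emulated study scale ($n = 26$, five modules of 30-80 genes with
  within-module correlation 0.5 over 500 background genes) module recovery
  is information-limited. An oracle classifier given the *true* latent
  factors attains an adjusted Rand index of only about 0.8 on average,
  because at $n = 26$ tens of background genes are sample-correlated with
  some factor as strongly as genuine members
  (Fisher-$z$ noise $1/\sqrt{23} \approx 0.21$ against a member/background
  separation of $\approx 0.88$). The package's pipeline performs at this
  oracle level (mean ARI $\approx 0.85$ across seeds), recovers the
  partition exactly in the noiseless limit, and exceeds ARI 0.9 reliably
  once $n \gtrsim 80$. Demands materially above the oracle bound at
  $n = 26$ cannot be met by any method on such data.
* With a single planted eigengene-trait effect of population $r = 0.75$
  among 104 null module-trait pairs at $n = 26$, the planted pair is
  detected at BH-adjusted $p < 0.05$ in roughly 85-90% of replicates — the
  remainder is the sampling probability that the observed correlation falls
  below the BH boundary — while the false-positive proportion among null
  pairs stays near $10^{-3}$, far inside the nominal 5%.

Problem sizes used by the tests and the acceptance script (hundreds to a
thousand genes, 20-50 replicate seeds per property) were chosen so the
whole suite completes in well under a minute while keeping Monte-Carlo
error comfortably below the asserted margins.

# Numerical choices and degenerate inputs

* Transcript collapse keeps the transcript with the highest arithmetic mean
  on the stored (log) scale; ties break by lexicographically smallest
  transcript ID. Row retention in `filter_top_expressed()` uses
  $\lceil \text{fraction} \times G \rceil$ — the only rounding consistent
  with 30% of 19,192 genes being 5,758 — with the same ID tie-break.
* Missing or non-finite expression values are rejected at ingestion; the
  correlation contracts assume complete matrices. Trait missingness is
  allowed and propagates through residualization with per-pair sample
  counts recorded.
* Zero-variance genes are an error in correlation (not silently dropped);
  zero-variance traits load with a flag and are skipped by the screens with
  a warning.
* All tie-breaks (transcript collapse, hub ranking, merge grouping) are
  deterministic, and the only randomness in the package is the simulator's
  seed, so identical configurations give bit-identical outputs.
* The guard `TOM = 1` at a non-positive denominator is unreachable for
  adjacencies in $[0, 1)$ and exists for the saturated-pair limit.

# Known limitations

Signed and signed-hybrid networks, biweight midcorrelation, blockwise and
consensus (multi-dataset) module detection, GO/pathway enrichment, and
longitudinal modeling of repeated clinical measures are out of scope. The
confounder screens assume independent samples. Exact reproduction of a
particular published module count from deposited data additionally depends
on that analysis's unreported tree-cut variant and block structure;
module-scale summaries (counts, size ranges, hub identities) should be
compared with that sensitivity in mind.
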