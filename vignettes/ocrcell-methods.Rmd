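---
title: "Cell-type-resolved chromatin accessibility: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-type-resolved chromatin accessibility: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocrcell)
library(dplyr)
```

## The problem

Bulk chromatin accessibility profiles of brain tissue mix signals from very
different cell populations, so both the discovery of regulatory elements and
case-control comparisons are confounded by cell composition. The pipeline in
this package analyses ATAC-seq data from sorted nuclei of four broad cell
populations — glutamatergic neurons (GLU), GABAergic neurons (GABA),
oligodendrocytes (OLIG), and microglia/astrocytes (MGAS) — across three
cortical regions (ACC, DLPFC, PVC), and then uses the cell-resolved open
chromatin regions (OCRs) as a reference panel to deconvolve and re-power a
bulk case-control study.

The pipeline stages are: consensus OCR construction and QC metrics
(`build_consensus()`, `frip()`, `pbc()`, `tss_enrichment()`);
promoter-anchored TMM normalization (`promoter_tmm()`, `log_cpm()`);
covariate screening and selection (`center_metrics()`, `pca_screen()`,
`bic_forward_select()`, `variance_fractions()`); precision-weighted
differential accessibility and specificity sets (`voom_weights()`,
`fit_contrasts()`, `cell_specific_sets()`, `group_specific_sets()`,
`region_specific_sets()`, `residualize()`); pi1 quantification
(`estimate_pi0()`, `pairwise_pi1()`); overlap and enrichment statistics
(`jaccard_bp()`, `great_enrichment()`, `tss_direct_map()`,
`eqtl_enrichment()`, `annotate_context()`); TF footprint burden
(`dedupe_sites()`, `prune_motifs()`, `burden_matrix()`, `rank_aggregate()`,
`motif_enrichment()`); and marker-based deconvolution
(`select_markers()`, `estimate_proportions()`, `casecontrol_workflow()`).
Every stage is exercised end to end on synthetic data from the
`simulate_*()` generators, which plant known effects and record them in a
truth object.

## The accessibility model

Counts of fragments overlapping each OCR are modelled on the log2
counts-per-million scale with weighted least squares:

```
accessibility ~ 0 + cell_type:region + sex + FRiP
```

The cell-by-region interaction is fitted as a single 12-level group factor
(means parameterization), sex contributes one column, and FRiP (fraction of
reads in peaks, a per-sample signal-to-noise metric) one numeric column — 14
model degrees of freedom in total (`model_df()`).

Cell-type contrasts compare cells **within the same region and average over
regions**, e.g. GLU vs GABA is `mean_r(GLU_r - GABA_r)`, so systematic
regional differences cancel. We divide the summed contrast by the number of
regions so that the reported log2 fold change is the average within-region
difference; significance is unaffected by this scaling, and marker
fold-change thresholds refer to this average.

Precision weights come from the voom machinery (`limma`): the mean-variance
trend of log-CPM provides observation-level weights and per-sample quality
weights down-weight noisy samples; the final weight is their product.
Quantile normalization is deliberately not used — cell types with different
promoter/non-promoter composition must not be forced onto a common count
distribution. Moderated t-statistics use empirical-Bayes variance shrinkage;
`moderate = FALSE` gives plain WLS t-tests.

## Promoter-anchored TMM normalization

Between-sample scaling uses the trimmed mean of M-values, but computed only
on OCRs that directly overlap an autosomal protein-coding TSS. Non-promoter
OCRs carry systematically lower counts, and their share of the library
differs by cell type; whole-matrix TMM consequently skews housekeeping
promoters toward apparent cell-type differences. Anchoring the factor on
promoter OCRs removes that skew.

Two further choices matter:

* **Library sizes are the promoter-submatrix column sums.** This makes the
  factors exactly invariant to adding or removing non-promoter OCRs, which
  is the property the promoter anchoring is meant to deliver. (The common
  alternative — subset M-values with whole-matrix totals — lets cell-specific
  distal OCRs re-enter through the library size.)
* **The factor for each sample is the mean over all reference choices.**
  TMM is defined relative to a reference sample; rather than privileging
  one, each sample's factor is averaged over every sample as reference,
  *including the trivial self-reference* (factor exactly 1). Including the
  self term is not cosmetic: every sample must average over the same
  reference set, otherwise the averages are not on a common scale (with two
  samples, a planted scaling ratio comes out squared). The per-sample
  standard deviation across reference choices is reported (`ref_sd`) as a
  robustness diagnostic. Factors are rescaled to geometric mean 1, where the
  linear-vs-log averaging question becomes immaterial up to a global
  constant; we average on the linear scale, the plain reading of "mean of
  the normalization factors".

The TMM internals (30% two-sided M-trim, 5% A-trim, delta-method precision
weights) follow the published TMM definition and match the `edgeR`
single-reference implementation exactly on the same submatrix (this is a
unit test, with `edgeR` as the independent reference).

`log_cpm()` uses `log2((count + 0.5) / (lib * factor + 1) * 1e6)`; the prior
count of 0.5 is the conventional default. It shrinks fold-change estimates
for OCRs with very few reads — see "Problem sizes" below.

## Covariate selection

QC metrics that sit on different scales per cell type are first divided by
their cell-type median (`center_metrics()`; an additive mode exists for
metrics that may be nonpositive). A per-cell-type PCA screen retains
components explaining more than 1% of variance, correlates candidates with
them, and applies Benjamini-Hochberg across all tests at a deliberately
lenient 0.2 — it is a screen, not the final selection.

The final selection is a greedy net-BIC forward search: a candidate is added
when at least 5% *net* of OCRs (improved minus worsened) change their BIC by
at least 2 — the conventional lower boundary of positive evidence — and the
remaining candidates are re-tested against the grown model until none
qualifies; squared terms of selected numeric covariates are then tested the
same way. Note that the "worse" side of the criterion depends on sample
size: with `n` samples a candidate that explains almost nothing still pays
`log(n)` BIC per coefficient, so at small `n` most null OCRs count as
worsened and net shares of useless covariates are strongly negative. Ties in
net share are broken lexicographically, which makes the selection invariant
to candidate ordering.

`variance_fractions()` decomposes each OCR's variance by sequential
(type-I) ANOVA in the order the covariates are given. Sequential sums of
squares partition the total exactly, so fractions plus residual sum to one
for every OCR — the invariant we test; on balanced designs such as the full
cell-by-region layout the decomposition is order-independent and coincides
with type-II sums of squares. For unbalanced designs the order matters and
should be chosen from design logic (design factors before technical
covariates).

## Specificity set algebra

An OCR is specific to cell type X iff it is significantly more accessible in
X than in *each* other cell type (two-sided FDR < 5% within contrast, with
positive fold change toward X). An OCR equally accessible in GLU and GABA
but low elsewhere is therefore specific to neither; it enters the broader
*Neuron* set, defined as the union over the two neuronal types of
(more accessible than both non-neuronal types); *nonNeuron* is the mirror
image. The implementation is tested exhaustively against a brute-force
evaluation of these set equations over all 2^6 pairwise-significance
patterns. For each member OCR the statistics of its least significant
qualifying comparison are reported (ties in p broken by smaller |log2fc|;
for the union sets, the most significant satisfied branch is reported).

Region specificity within a cell type contrasts one region against the mean
of the others, restricted to OCRs called open in that cell type, with BH
recomputed over the restricted set only — the restriction is the power gain.

## pi1: how different are two groups?

The proportion of non-null tests, pi1 = 1 − pi0, summarises each of the 66
pairwise group comparisons (12 cell-by-region groups). pi0 is estimated with
the lambda-grid smoother: `pi0(lambda) = #{p > lambda}/((1 - lambda) n)` on
`lambda = 0.05 ... 0.95`, cubic-spline smoothed (df = 3) and read off at the
largest lambda, clamped to [0, 1]. The convex-decreasing estimator
(`limma::convest`) is available as an alternative and serves as an
independent cross-check in the tests. The smoother is calibrated under
alternatives concentrated well below the lambda grid; the synthetic p-value
generator therefore defaults to Beta(0.02, 1) alternatives. Heavier-tailed
alternatives (shape near 1) leak mass above lambda = 0.95 and bias pi1
downward for any estimator of this family.

## Footprint burden and motif enrichment

Footprinted binding sites (with binding probabilities, e.g. from a
footprinting model) are first deduplicated per motif — among mutually
overlapping sites the highest-probability one is kept (ties: leftmost) —
then motifs are pruned for redundancy: two motifs are redundant when at
least half of the smaller motif's sites each overlap a site of the other by
at least half of the shorter site's length; the most redundant pair loses
its smaller member (ties lexicographic) until no redundant pair remains.
Without pruning, factors sharing a motif would be double-counted.

A site's influence on a gene is `p_bind * exp(-d / decay_scale)` with `d`
the distance from site midpoint to the gene's nearest TSS, zeroed beyond
`10 * decay_scale`. The decay constant defaults to 10 kb — a scale at which
promoter-proximal sites dominate but enhancers within ~100 kb still
contribute; it is a free parameter and exposed as such. Gene-level burden
sums these weights per sample group; group comparisons use centered ranks
`-(n-1)/2 ... (n-1)/2` of per-pair burden differences, averaged over all
cross-side pairs (each pair's ranks sum to zero by construction, and
swapping sides negates all scores).

Motif over-representation in cell-specific OCRs uses a one-sided binomial
test that accounts for coverage: under the null a bound site falls in the
target set with probability equal to the target's share of covered base
pairs; Bonferroni correction over motifs.

## Deconvolution and the case-control workflow

Markers are cell-specific OCRs at FDR < 5% and log2 fold change > 2 against
*every* other cell type — stringent thresholds that make the panels disjoint
by construction. Proportions in bulk samples solve a linear mixing model on
linear-scale CPM over the marker OCRs: nonnegative least squares with the
overall scale profiled out, the estimate being the normalized coefficient
vector. Profiling the scale (rather than forcing the coefficients themselves
to sum to one inside the residual) makes the estimate invariant to the
overall scale of both the bulk CPM vector and the reference matrix, so unit
mismatches between reference and bulk cannot bias the proportions; the
reported proportions still lie on the simplex.

The case-control workflow fits the diagnosis contrast twice: with the base
model (diagnosis plus any always-in technical covariates such as a GC-like
metric), and with the estimated proportion columns that pass the same
net-BIC selection used in the sorted study. The proportions sum to one, so
one column is redundant given the intercept; the selection detects and skips
the singular candidate with a warning. Normalization inside this workflow
uses whole-matrix TMM (`tmm_factors()`): a planted disease effect (or
composition shift) changes other OCRs' read share at fixed depth, and the
trimmed mean absorbs exactly that compositional artifact. pi1 of the
diagnosis p-values measures detectable disease signal under each model and
within each cell type's specificity set.

## What the synthetic data emulates — and what it does not

`simulate_sorted_experiment()` draws negative-binomial counts whose
expectation is baseline x planted cell effect x region effect x sex effect x
FRiP allocation, rescaled to each sample's library size. FRiP acts as a
signal-allocation fraction: signal OCRs scale with `frip/mean(frip)`,
background OCRs with `(1-frip)/(1-mean(frip))` — the "signal-to-noise"
role FRiP plays in real data. Sex effects sit on a small set of chrX OCRs.
Defaults mirror the sorted-nuclei design: 4 cell types x 3 regions x 4
subjects (48 samples; the real study lost one sample to QC), promoter share
0.3, planted log2 fold changes of 2, NB dispersion 0.05 (biological-replicate
scale), FRiP in 0.2-0.6.

`simulate_reference_profiles()` builds per-cell-type accessibility profiles
with two features real sorted chromatin shows: a strong marker set per cell
type, plus broad genome-wide differences (lognormal per-cell perturbation,
`profile_sdlog = 0.3`, set so that composition explains roughly the ~10% of
per-OCR variance reported for deconvolution covariates in bulk brain
chromatin). A separate, less extreme "cell-specific" OCR set per cell type
mimics the fact that specificity sets in a sorted study are much larger and
mostly disjoint from the stringent deconvolution marker panel.

`simulate_bulk_mixtures()` mixes the (column-normalized) reference profiles
with Dirichlet proportions at fixed depth, plants a case effect
multiplicatively on top of the depth-normalized mixture, and optionally adds
a GC-like allocation covariate. For power simulations,
`balance_composition = TRUE` assigns each drawn proportion vector to one
control and one case, making composition exactly independent of diagnosis in
the sample — without it, chance composition-diagnosis correlation in finite
samples creates genuine (but design-artifact) diagnosis signal in the
unadjusted model, which is precisely the confounding the composition
covariates exist to remove, but which makes a two-model power comparison
noisy at simulation scale.

What the generators do *not* emulate: read-level artifacts (GC and mappability
bias at base resolution, duplication structure), subject-level random effects
and batch structure, LD or genotype effects, chromatin domain correlation
between nearby OCRs (counts are independent across OCRs given the design),
and open-ended peak discovery (the OCR set is fixed). Passing tests
demonstrate correctness of the statistical machinery under the stated
generative model, not robustness to all the failure modes of real
libraries.

## Problem sizes and numerical choices

The test-suite and acceptance-script simulations are sized for a desk-scale
run: 250-5,000 OCRs, 12-48 sorted samples at ~1e6 reads each, bulk
case-control runs with 800 OCRs and 200 samples at 2e6 reads, 50-100 seeds
for rate-based checks. Two consequences of desk scale are handled
explicitly:

* At 1e6 reads, an OCR at 1 CPM carries ~1 read, and the 0.5 prior count
  shrinks its fold-change estimate severely; a real study at ~65M reads has
  65 reads at the same CPM. Fold-change *recovery* is therefore evaluated on
  OCRs with expected mean counts >= 64 — the counting precision the real
  study's lowest-accessibility retained OCRs have — and at technical-scale
  dispersion (0.01); estimator *bias* and p-value calibration are checked at
  the realistic biological dispersion (0.05), where single-OCR recovery
  bands would be dominated by biological sampling noise (sd ~0.13 for a
  12-vs-12 comparison) rather than by the estimator.
* The case-control disease effect is planted at log2fc 0.25 on one cell
  type's specificity set: subtle effects are the realistic regime for
  psychiatric case-control chromatin, and a strong planted effect would leak
  into the estimated proportions (deconvolution contamination), an
  interesting phenomenon but not the power question the workflow answers.

Other numerical choices: TMM trims 30%/5% with delta-method weights
(configurable); the voom trend span is 0.5; the mixing QP adds a relative
ridge of 1e-8 for conditioning; permutation p-values are
`(1 + #{OR_perm >= OR_obs}) / (1 + n_perm)`; degenerate 2x2 tables get
Haldane-corrected odds ratios and a flag; TSS-enrichment returns 0 for empty
windows and `Inf` when there is TSS signal but a literally empty flank
baseline (the per-bp pileup definition, stated rather than hidden).

## Known limitations

* The TSS-enrichment aggregation is a simple per-bp pileup contract (center
  over outermost-100-bp baseline); dedicated QC tools implement more
  elaborate smoothing and housekeeping-gene restriction.
* The sample-weight estimation is delegated to the voom quality-weight
  machinery; no duplicate-correlation or random-effect structure is
  modelled, so subject-level pseudoreplication in designs with repeated
  subjects is only partially absorbed.
* `estimate_proportions()` assumes the reference panel is itself unaffected
  by the condition under study; a disease effect on marker OCRs biases the
  estimated proportions toward the affected cell type.
* Burden scores treat binding sites independently; cooperative or
  competitive binding is out of scope.
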