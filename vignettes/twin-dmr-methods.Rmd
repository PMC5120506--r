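---
title: "Detecting DMRs in small discordant twin cohorts: methods and design choices"
author: "twindmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting DMRs in small discordant twin cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twindmr)
```

## The problem

Discordant monozygotic twin designs remove genetic background from
epigenome comparisons, but clinical twin collections are small — often
five to ten pairs. At that sample size, probe-level tests on a
multi-million-probe tiling array find nothing after multiple-testing
correction, while naive region-level scans drown in false positives
driven by single extreme pairs and by cell-composition differences in
whole blood. `twindmr` implements a high-specificity region-level
framework built for exactly this regime: it prioritizes true positives
and accepts low sensitivity as the price.

## The model

### Probe-level paired model

Methylation proportions $p_{js}$ (probe $j$, sample $s$) are transformed
to M-values $M = \log_2\frac{p}{1-p}$ (clamped to $[\varepsilon,
1-\varepsilon]$, $\varepsilon = 0.01$), which stabilizes variance for
linear modeling. Per probe we fit ordinary least squares

$$ M_{js} = \alpha_{j,\mathrm{pair}(s)} + \beta_j \,
\mathrm{case}(s) + \gamma_j^\top z_s + e_{js}, $$

with one fixed effect per twin pair, a phenotype indicator, and
optionally three cell-proportion covariates $z_s$. The pair fixed
effects implement the paired design: without covariates, $\hat\beta_j$
is algebraically the mean within-pair M-value difference. Pairing via
fixed effects rather than explicit differencing was chosen because it
admits sample-level covariates naturally.

The covariate triple (neutrophil, NK, CD4+CD8 T) sums to one and is
therefore collinear with the pair-intercept block; the fit drops the
redundant column by QR pivoting and records it. The phenotype
coefficient is unchanged by which column is dropped, since the column
space is identical. The fit refuses to proceed only when the phenotype
indicator itself is confounded (removing its column does not lower the
design rank).

### Candidate discovery (bump hunting)

Per-probe coefficients are smoothed along the genome *within* each
design region — robust locally weighted regression (span 0.75, two
robustness iterations); regions with fewer than four probes use a
centered running mean of window 3. Smoothing never crosses region
boundaries. Candidate DMRs are maximal runs of consecutive probes with
$|\text{smoothed } \beta|$ at or above a cutoff (default: the 0.995
quantile of all smoothed magnitudes), a consistent sign, inter-probe
gaps of at most 300 bp, and at least 3 probes. The cutoff quantile,
minimum probe count and gap are tunables with no canonical values; the
defaults were fixed once for the 10-sample regime and are exposed in
`run_config()`.

Each candidate carries three statistics on the *proportion* scale
(the model runs on M-values, but effect sizes are reported as
percentage-methylation differences): `avg`, the mean per-probe
case-minus-control difference; `max`, the signed per-probe difference of
largest magnitude (hypomethylated regions keep their negative sign); and
`area_raw` = nprobes × avg.

### Within-pair sign-flip permutation

Small paired cohorts are vulnerable to locus-specific outliers: one
extreme pair can push a region statistic past any global threshold. The
local check summarizes each sample over the candidate (mean or max of
methylation), takes the mean over pairs of the case-minus-control
summary differences, and enumerates all $2^n$ within-pair label swaps
(5 pairs → 32, 7 pairs → 128). The two-sided p-value is the fraction of
assignments — identity included — whose $|$statistic$|$ reaches the
observed one, so exhaustive p-values are multiples of $1/2^n$ and never
zero. Beyond a configurable cap (default 4096) the enumeration switches
to Monte-Carlo with an explicit seed and the add-one convention.

A candidate is *excluded* when its permuted p exceeds 0.1 for **both**
the average and the maximum statistic. The conjunction matters: an
outlier pair inflates the observed statistic but cannot make the
sign-flip p small, whereas a consistent effect across pairs can. The
filter runs at discovery **and inside every resampling iteration** —
filtering only the observed run while leaving the null pool unfiltered
would inflate the null maxima and deflate everyone's FWER.

### Stratified bootstrap FWER

Global significance is a resampling family-wise error rate computed per
statistic. The default null scheme refits the model without the
phenotype term, resamples whole residual *columns* (samples) with
replacement on the M scale, and adds them back to the null fitted
values; this preserves the probe-correlation structure that region
statistics feed on. Within-pair label permutation is available as an
alternative scheme. Each of the $B$ iterations re-runs the entire
candidate pipeline — same absolute cutoff resolved on the observed data,
same smoothing, same permutation filter.

Because `area_raw` grows with probe count, comparing every candidate
against a global null maximum biases calls toward long regions. The
FWER is therefore stratified by probe count: null candidates are binned
by quartiles of their probe counts (bins with fewer than 20 null
observations merge into their nearest neighbor; fixed edges can be
supplied), and a candidate is compared only against the per-iteration
maximum $|$statistic$|$ within its own bin. Iterations with no null
candidate in the bin contribute a maximum of zero. An estimate of
exactly zero is reported as "< 1/B" via the `fwer_floor` column rather
than given a pseudo-count.

A DMR passes the dual criterion iff at least one of the three FWERs is
at or below 0.10 (a relaxed 0.20 reporting threshold is also exposed)
**and** the smaller permuted p-value is below 0.1. The FWER comparison
uses absolute statistics; whether signed or absolute comparison is more
appropriate is genuinely open, and absolute was chosen as the
conservative two-sided option. $B$ defaults to 2000 for production
runs; the calibration suites in this package use $B = 200$.

## Cell-type deconvolution

Whole-blood methylation differences between discordant twins are often
cell-composition differences in disguise. The reference-based estimator
proceeds in four steps: (1) one-vs-rest marker discovery on sorted-cell
profiles using the same bump-hunting machinery at a fixed effect cutoff
of 0.1 and a 2-probe minimum (sorted-cell contrasts are large, so the
lowered cutoff is safe); overlapping intervals from different contrasts
are merged; (2) a reference matrix $B$ (cell types × markers) of mean
methylation over each marker's probes; (3) selection of the $k = 300$
most informative markers by the F-statistic of a one-way fit on
cell-type labels, ties broken by genomic order; (4) per bulk sample, a
constrained least-squares fit

$$ \hat w = \arg\min_{w \ge 0,\ \sum_k w_k = 1} \lVert x - B^\top w
\rVert^2 ,$$

solved exactly by enumerating active sets and solving each
equality-constrained KKT system — deterministic and exact for panels of
a few cell types, verified against a 0.001-step simplex grid search.
Markers lost to probe QC are dropped pairwise and the fit re-solved on
the survivors. The model covariates are the neutrophil proportion, the
NK proportion, and the summed CD4+CD8 T proportion.

What covariate correction can and cannot absorb: on the proportion
scale, mixture signal at a marker probe is $e \cdot w_{k}$ for the
designated cell type $k$. Neutrophil- and NK-driven signal lies in the
covariate span; a CD4-vs-CD8 contrast does not (only their sum is a
covariate), and the M-transform makes the relationship only locally
linear. Correction therefore *attenuates* composition-driven
coefficients strongly (an order of magnitude in the package's tests)
rather than nulling them exactly.

## Downstream analyses

Projection takes intervals called in one cohort and computes the
sign-flip permutation p-values (avg and max) on *another* cohort's data;
the two directions are independent computations, and intervals without
probes in the target design are flagged untestable. Replication support
is quantified by directional consistency (fraction of sign-agreeing
nonzero difference pairs) and by meta-analysis: Edgington's
summation-of-p with the exact Irwin–Hall CDF, and inverse-variance
fixed-effect pooling with Cochran's Q as the homogeneity check (the
fixed-effect model is appropriate when Q does not reject). Confounder
screens regress per-pair DMR summaries on age, sex, smoking, or HLA
shared-epitope status and test the slope; distributional skew between
sample strata is compared with a two-sample Kolmogorov–Smirnov test on
the top differentially methylated probes (how many "top" probes is
unspecified in any source; 1000 is the default parameter).

## The synthetic generator

`generate_array_design()` emulates a CHARM-like layout: regions of 8–12
probes tiled at 30–100 bp spacing (typical tiling density; no canonical
value exists), regions at least 1 kb apart, and ~2% CpG-free control
probes placed in inter-region gaps. Probe quality scores are drawn
Uniform[60, 100] so the quality-80 filter has realistic work.
`generate_cell_reference()` plants one designated outlier cell type per
marker region at an effect of at least 0.2. `simulate_twin_cohort()`
composes each sample as a mixture over the reference profiles with
Dirichlet weights (default concentration (12, 4, 2, 2), centering the
mixture near 60/20/10/10 — realistic for these four leukocyte types in
whole blood), a pair-shared baseline perturbation (sd 0.02) that paired
differencing removes — the monozygotic-twin similarity the design
exploits — the planted phenotype effect at chosen regions, and Gaussian
noise on the proportion scale clipped to [0, 1]. Clipping (rather than
logit-normal noise) keeps the planted delta exact in expectation away
from the boundaries.

What the generator does *not* emulate: array scanner physics, dye bias,
restriction-fragment effects, CpG-density bias, or a realistic batch
model (a constant per-batch intercept is available but makes no claim
of realism — no generative batch model is described in any source).
Passing tests therefore demonstrate the statistical machinery is
correct and calibrated under the stated noise model, not that the
pipeline is robust to real array artifacts.

The optional two-channel emission (`emit_two_channel()`) is stylized:
total intensity log-normal, treated channel a $p$ share of it, so the
ratio estimator is exact by construction. It exists to exercise the
normalization code path, not to model hybridization chemistry.

## Numerical choices

* M-value clamp $\varepsilon = 0.01$; configurable.
* Smoothing: `stats::lowess`, span 0.75 within regions, 2 robustness
  iterations; running mean (window 3) below 4 probes.
* Cutoff ties: inclusive ($\ge$) at the cutoff boundary.
* Permutation ties: $|$stat$| \ge |$observed$| - 10^{-12}$, so exact
  ties (including the identity) always count.
* Subset quantile normalization evaluates quantile curves on a grid
  that includes the control order-statistic probabilities, making the
  control-anchored map exact for tie-free data; beyond the control
  range the map extends with slope 1 (values are shifted, not
  collapsed). With boundary atoms (values clipped to 0 or 1) exact
  quantile equality across samples is unattainable by any monotone
  value map; the property holds exactly on continuous data.
* The QP enumeration accepts a support when its KKT solution is
  nonnegative within $10^{-9}$ and prefers strictly smaller objectives
  ($10^{-12}$ margin), so the solution is deterministic under ties.
* Degenerate inputs: constant samples in quantile normalization map to
  the reference median with a warning; zero-variance paired differences
  give t = 0, p = 1 by convention; empty candidate lists and empty
  null strata are legal and flow through.

## Problem sizes in the validation suites

The packaged test suites run the full pipeline at 500 regions ×
~10 probes (~5100 probes), 5 twin pairs, $B = 200$: planted-effect
recovery over 20 replicates, all-null specificity over 100 replicates,
and deconvolution recovery at 300 markers. These sizes keep a laptop
run in minutes while preserving every structural feature of the
full-scale analysis (the same code paths run unchanged at
2.1M probes; only `B` and the replicate counts are scaled).

## Known limitations

* Specificity is the objective; with five pairs the design has low
  sensitivity by construction, and weak effects (below ~0.1 on the
  proportion scale over few probes) will usually be missed.
* Reference-based deconvolution is limited to the supplied panel; a
  cell type missing from the reference biases the estimated weights of
  the others. Reference-free methods are out of scope.
* Batches are never compared statistically; the package enforces
  one-batch-per-run structurally and offers no cross-batch correction.
* FWER stratification bins ("similar number of probes") have no
  canonical definition; quartile bins with a 20-observation minimum are
  a reasonable default, and fixed edges can be supplied when
  comparability across runs matters.
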