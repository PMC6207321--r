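---
title: "Methods: synthetic neutrophil cohorts and the control-anchored response model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic neutrophil cohorts and the control-anchored response model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floodr)
```

This vignette documents the scientific and numerical choices behind floodr:
what the synthetic cohort generator emulates (and what it deliberately does
not), how the gating, statistics and single-cell response model are defined,
and where the design was genuinely open.

## The study design being emulated

The package targets a repeated-measures design in which ~28 subjects give
blood at six occasions around a multi-day endurance event: evenings of days
0, 4 and 7 (directly post-exercise) and mornings of days 1, 5 and 8 (after
overnight recovery). Each sample yields an automated-counter leukocyte
concentration and an event-level 12-channel cytometry measurement (FSC, SSC
and ten fluorescence markers: CD35, CD64, CBRM1/5, CD11b, LAIR-1, CD14,
CD16, CD62L, CD49d, CD66b). Neutrophils are identified by scatter plus
CD66b⁺CD16⁺ gating and partitioned into three CD16/CD62L quadrant subsets;
the double-dim quadrant is not a recognised subset and is counted but
excluded. Morning day 1 is the control state; everything else is response.

## The synthetic cohort generator

`simulate_cohort()` draws, per subject and occasion, an event table plus a
counter concentration. Its structure:

* **Mixture.** Events come from the three neutrophil subsets plus one
  generic "other leukocyte" cluster (CD66b-negative, CD14/CD64-high,
  lower side scatter) whose only job is to exercise the gate. Labels are
  drawn multinomially with probabilities proportional to the realised
  population concentrations, and the latent label is retained in a
  `.label` column that gating never sees — tests use it to measure recall,
  precision and label accuracy.
* **Concentrations.** Per-occasion cohort mean concentrations of the three
  subsets are the calibration anchors (`default_subset_concentrations()`):
  the total is anchored to the published per-day cohort means and split
  proportionally to the published subset means (which sum to slightly less
  than the printed total; the split is renormalised so the *total* is
  exact). Evening occasions use published evening totals with the nearest
  morning's composition. Each subject carries one mean-one log-normal
  concentration factor (CV 0.30) shared across occasions; each population
  in each sample carries additional mean-one log-normal noise (CV 0.25).
  The counter concentration is the realised total of all populations, so
  counter × gated fraction is an unbiased estimate of the configured means.
* **Fluorescence.** Intensities are log-normal around the subset median:
  location = log(median × time multiplier × subject factor), scale from a
  per-cell CV (default 0.50; scatter 0.12). Time multipliers for the six
  phenotype markers are the published pooled-neutrophil MFI ratios relative
  to morning day 1 (evenings borrow the nearest morning's multiplier; day 0
  is baseline). Per-subject, per-marker median-one log-normal factors
  (CV 0.30) reproduce the between-subject heterogeneity seen in individual
  time-course plots (e.g. the high/low LAIR-1 responder groups). Because
  the subject factors are median-one (not mean-one), cohort *mean* MFIs run
  a few percent above the nominal medians; fold changes are unaffected.
* **Correlated control structure.** A per-cell median-one log-normal
  "granule content" factor (CV 0.35) multiplies the granule-associated
  channels CD35, CD64, CD11b and CD66b. Resting neutrophils co-express
  these degranulation markers, and in the reported response-model geometry
  their loadings are orthogonal to the activation markers — so this factor
  supplies a real, structured control-variance direction that is distinct
  from the response direction. It is the direction the control subspace of
  the response model is expected to capture.
* **Negative values.** Zero-centred Gaussian background noise (SD 15 a.u.)
  is added to every fluorescence intensity after the log-normal draw, so a
  small fraction of intensities is negative — exactly what instrument
  background subtraction and compensation produce, and what the
  shift-to-positive preprocessing step exists for.
* **Sizes.** Default 20,000 events per sample (the assay stains 500,000
  cells; scaled for desk-speed simulation — tests and the acceptance script
  use 1,000–5,000 events per sample, stated per analysis).

`simulate_lps_sample()` reuses the same machinery with the acute
endotoxemia phenotype: CD35 and CD11b medians raised (×2.5, ×2.0), CD16 and
LAIR-1 lowered (×0.5 each) on all neutrophils, prominent CD16-dim and
CD62L-dim subsets (fractions 0.25/0.35 vs 0.40 normal), and extra CD11b
(×1.8) on the CD62L-dim subset. The override *directions* are fixed; the
magnitudes are package choices (the source tables give none) and are
configurable.

What the generator does **not** emulate: doublets and debris (the singlet
gate is a pass-through hook), spectral spillover, acquisition-time drift,
eosinophil/lymphocyte realism beyond the single generic cluster, and
per-subset MFI differences (published per-subset differences are small; the
subsets share medians except for CD16/CD62L). Passing tests therefore
demonstrate correctness of the *pipeline* under a faithful statistical
structure, not instrument-level realism.

## Gating

Thresholds are closed on the bright/positive side — an event exactly at a
threshold is positive — so gates are deterministic and tie-breaks
well-defined. Defaults (`subset_gates()`) sit at the geometric mid-points
between the configured modes (CD66b 400, CD16 bright/dim split 2200, CD62L
split 1100, CD16 positivity 100 a.u.). `derive_gates()` provides the
data-driven analogue of manual gating: each threshold is the
minimum-density valley of the log₁₀ histogram between the two main modes,
with a low-quantile fallback (5th percentile) when the distribution is
unimodal. CD14 was in the panel but its use for monocyte exclusion is not
documented in the source protocol; a CD14 ceiling is implemented but off by
default, since CD66b gating already excludes the CD66b-negative cluster.

## Repeated-measures statistics

`rm_anova_oneway()` computes the balanced within-subject decomposition on
complete cases (subjects missing any analysed occasion are excluded and
reported — the source protocol excluded two such subjects). The omnibus F
is MS(time)/MS(subject×time). All pairwise contrasts reuse that error mean
square. Three choices were genuinely open:

* **Multiplicity.** The source analysis software defaults to Tukey's HSD
  for all-pairs comparisons but the correction is never named; we use
  Tukey's studentised range on the RM error term (`adjust = "none"` gives
  plain t intervals). Published p-values are therefore not expected to be
  reproduced digit-for-digit.
* **Fold-change CI.** The fold change is the ratio of time-point means;
  its CI maps the mean-difference CI through
  (baseline + bound)/baseline. This reproduces the published pattern
  (fold CIs bracketing the fold estimate symmetrically) without claiming
  to match an undocumented procedure.
* **Sphericity.** No correction is applied by default (none is mentioned
  in the source); the machinery is the standard univariate decomposition,
  so a Greenhouse–Geisser style correction can be layered on the printed
  df if needed.

`rm_anova_twoway()` (both factors within-subject, e.g. subset × time for
per-subset MFIs) tests each effect against its matching
subject-interaction mean square. Per-cell contrasts are simple-effect time
contrasts within each subset level, computed with the one-way machinery —
this makes the single-subset case reduce *exactly* to the one-way fit, a
property the tests assert.

## The control-anchored response model

Preprocessing follows the published recipe literally: subtract
(global minimum − 1) so the pool minimum is exactly 1, log-transform, then
centre and scale per marker using the pooled control cells only. We fix
log base 10; any base change rescales all log values by a constant which
standardisation cancels, so the choice is cosmetic but frozen for
reproducibility. SDs use the sample (n−1) convention throughout. The shift
constant is fitted once on the union of control and response cells of an
analysis and reused for every sample in it, making preprocessing a single
map.

The response-specific model itself is a declared reconstruction: the
original method's algorithmic detail lives in a separate methods paper, and
the implementation here is the most direct reading of "orthogonal
orientation" plus "variation within the response group best explained" —
control-subspace PCA, orthogonal deflation of the response pool, then PCA
of the deflated (centred) response pool. Every downstream quantity is
defined against this decomposition, and its internal consistency is what
the oracle tests check (dense eigendecomposition agreement at 1e-8,
deflation orthogonality at 1e-8). The published explained-variance figures
(54% = 33% + 21%) depend on the unavailable real cohort and are not
reproduction targets.

Numerical conventions: loadings are sign-fixed (largest-magnitude element
positive) so repeated fits are bit-identical; eigenvalues are clipped at
zero; rank deficiency below the requested component count is an error.

**Choosing k_c.** The default rule (smallest number of control components
explaining ≥90% of control variance, capped at markers − k_r) mirrors
common PCA practice, but it is only sensible when the control spectrum has
structure. After per-marker standardisation a synthetic control pool is
close to isotropic apart from the granule direction, so the 90% rule would
consume nearly the whole marker space and the cap (8 of 10 markers) leaves
a 2-dimensional response space — harmless for benchmark coverage, which
holds by construction, but destructive for loading interpretation, since
deflating near-arbitrary directions scrambles weak markers. The package's
validation analyses therefore pass an explicit `k_c = 1`: the single
eigenvalue-separated control component (the granule direction). For real
data the advice is the same — inspect the control scree and keep only
clearly separated components.

**Benchmarks.** The 80% region is the Mahalanobis ellipse of the defining
scores with squared radius at the empirical 80% quantile (inverse-ECDF
type), so the inside fraction of the defining cells is within 1/n of
nominal by construction, and on standard bivariate normal scores the
fitted radius converges to the χ²(2 df) 0.80 quantile (3.219) — both are
test oracles. An ellipse rather than a kernel-density contour keeps the
region closed-form and testable; per-sample benchmarks (the dark blue/red
rings of the biplots) are refit per sample with that sample's own score
covariance — whether the original used pooled or per-sample covariance is
unstated, so this is configurable by construction of the API
(`benchmark_region()` on any score set). Benchmarks need ≥50 defining
cells; below that `fit_flood()` leaves the benchmark out.

**Expected geometry.** With the default calibration the response pool's
within-pool time contrast (the near-baseline evening-day-0 cells against
late-tour cells) makes CBRM1/5, CD49d and LAIR-1 load together in the
response plane, and the day-8 population shift aligns with those loadings
and opposes the CD62L loading (the CD62L-dim subset triples by day 8).
Note that CD62L's own loading *orientation* is dominated by its large,
time-independent dim/bright bimodal variance, so its raw loading signs are
noisy around zero; the stable, tested statement is about the alignment of
the day-8 shift with the loading vectors.

## Problem sizes and determinism

All simulations are seeded and bit-reproducible given (config, seed). The
test suite runs cohorts of 1–28 subjects at 1,000–20,000 events per sample
(about a minute in total); the acceptance script uses 28 subjects × 3
morning occasions at 5,000 events per sample for benchmark coverage
(~140,000 control cells) and 20 seeds × 28 subjects at 1,200 events per
sample for the fold-change recovery — sizes chosen so each quantity's
Monte-Carlo error is well inside the tolerance being checked while the
whole script stays desk-fast.

## Known limitations

* The response-model decomposition is a reconstruction (above); numerical
  identity with the original software is not claimed.
* The FCS codec writes the FCS 3.0 float dialect and reads
  single-dataset 2.0/3.0/3.1 float/double files; TEXT values containing
  the delimiter, integer data types and multi-dataset files are out of
  scope.
* Printed p-values from the source tables are not reproduction targets
  (unknown multiplicity procedure, unavailable raw data); only arithmetic
  derived from printed means and the simulation-calibrated quantities are.
* The two-way RM-ANOVA assumes balanced complete cells after complete-case
  filtering, as in the emulated design; unbalanced designs need a
  mixed-model approach outside this package's scope.
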