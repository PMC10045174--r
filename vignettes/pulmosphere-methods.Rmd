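---
title: "Methods: quantifying pulmosphere invasion and antifibrotic response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying pulmosphere invasion and antifibrotic response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulmosphere)
library(dplyr)
```

## The assay and its statistic

A pulmosphere is a 3-D multicellular spheroid grown from a patient's primary
lung tissue and embedded in collagen. Over roughly a day, cells invade
outward from the dense spheroid core into the matrix; the extent of that
invasion tracks the fibrotic activity of the source tissue. Two areas are
measured per spheroid image: the core area $R$ and the total invaded area
$H$ (core plus everything the invading cells cover). The invasiveness
statistic is the zone-of-invasion percentage

$$\mathrm{ZOI\%} = \frac{H - R}{R} \times 100,$$

which is zero when nothing invades and is invariant under any common
rescaling of $H$ and $R$ — microscope calibration (microns per pixel) can
never change it, which is why the pipeline defaults to reporting raw pixel
areas.

Drug response is scored per patient and drug. Each of the (typically 5)
spheroids in a treated arm yields a fold change: its ZOI% divided by a
location summary of the same patient's untreated replicates. A patient is a
**responder** when the **median** fold change is strictly below 1; exactly 1
is classified nonresponsive, because response is defined as a strict
reduction. Response rates over a cohort carry exact Clopper–Pearson 95%
confidence intervals, and the integer percent is formed by truncation
toward zero (6/11 prints as 54%, not 55%) — the convention under which the
reported whole-percent rates and their counts are mutually consistent.

Because treated and untreated spheroids are physically distinct replicates,
no natural pairing exists between them. We divide every treated replicate
by the **median** of the patient's untreated replicates (a robust location
summary); a mean denominator is available via `run_config(denominator =
"mean")`. This was a genuinely open design point: with 5 replicates per arm
and multiplicative noise, the median denominator keeps a single aberrant
untreated spheroid from inflating or deflating all of a patient's fold
changes.

## Image quantification

The reference workflow outlines $H$ and $R$ by hand. This package
substitutes an automatic, reproducible procedure, while hand-drawn ROI
tables remain first-class inputs (`pipeline_quantify()` accepts a CSV of
`H`/`R` values and bypasses segmentation entirely, so scoring never depends
on the segmenter).

1. **Foreground segmentation** (`segment_foreground()`): threshold by
   Otsu's method (or a fixed cut), fill enclosed holes, drop connected
   components below `min_component_size` (default 5 px). An empty
   foreground is an error, never a silent zero.
2. **Core isolation** (`measure_core_area()`): a morphological opening.
   The mask is eroded by `erosion_radius` — by default 1/4 of the
   equivalent-circle radius of the largest component, large enough to
   delete single-cell strands and small enough to keep the core — the
   largest surviving component is the core seed, and the seed is dilated by
   the same radius within the original mask. Two numerical choices matter
   here:
   - Erosion and dilation use the **Euclidean distance transform** rather
     than a discrete brush, with a 0.75 px slop on the dilation radius
     (capped by the mask): under a discrete brush a digital disk loses its
     four axis-extreme pixels in the round trip, whereas this construction
     returns solid disks exactly (verified for radii 3–80), which is what
     makes noiseless synthetic cores exactly recoverable.
   - Cells merged with the core rim survive erosion as local bumps on the
     seed and would otherwise be re-captured whole by the dilation; a
     second opening of the seed at 1.5× the radius shaves single cells and
     small clusters while leaving a disk-shaped seed unchanged.
3. **Total invaded area** (`measure_total_invaded_area()`): either the
   convex hull of all foreground pixels (default; mimics outlining the
   outer invasion front by hand) or the raw foreground pixel count
   (`component_union`). Hull area is counted as the number of pixel centers
   inside the hull polygon, so areas are whole pixels with no sub-pixel
   interpolation, and hull $H$ always dominates the pixel union, hence the
   core — the geometry constraint $H \ge R$ holds by construction.

Areas are reported in px²; setting `um_per_px` in `run_config()` rescales
them to μm². The magnification of the source images is deliberately left
configurable because ZOI% does not depend on it.

## The synthetic-data generator

Every stage is testable without experimental data because the generator
produces both levels of the problem with known ground truth.

**Images** (`generate_pulmosphere_image()`): a bright filled disk (the
core, intensity 0.9) with `n_cells` Gaussian-profile blobs (sigma 2–4 px,
amplitude 0.8) scattered area-uniformly at radii in
`(core_radius, core_radius + reach]`, over Gaussian background noise
clipped to [0, 1]. Blob support is cut at intensity 0.25, so the
ground-truth invasion mask is exactly the set of pixels with nonzero
noise-free intensity — a noiseless image thresholded below the cut
segments *exactly* to its truth mask, which pins down the zero-noise end
of every recovery test. Geometry that would clip the invasion zone at the
border is rejected. Ground-truth `truth_R`/`truth_H` are literal mask pixel
counts, so `component_union` measurements have an exact oracle; the convex
hull exceeds the union by construction, and hull-based recovery is tested
in a dense-invasion regime (many cells, short reach) where envelope and
union nearly coincide.

**Cohorts** (`cohort_spec()` + `generate_cohort()`): the defaults *are* the
emulated study conditions — 23 ILD patients (12 CTD-ILD, 6 unclassifiable,
4 smoking-related, 1 hypersensitivity pneumonitis, allocated by largest
remainder for any `n_ild`) versus 9 explant-donor controls; baseline ZOI%
normal with mean 516.2, SD 115.6 (ILD) and mean 54.63, SD 19.6 (control),
truncated at 0 by resampling; 5 replicates per arm with lognormal
multiplicative replicate noise (sigma 0.15, i.e. ~15% CV — chosen as a
typical replicate spread for a ratio-scale assay; lognormal keeps ZOI%
positive with roughly constant CV). Per-patient drug effects are lognormal
multipliers centred on the treated/untreated mean ratios of the emulated
arms (nintedanib 192/516.9 ≈ 0.37, pirfenidone 512.3/581.2 ≈ 0.88, sigma
0.30). Responder status is drawn per patient as Bernoulli with the
specified `responder_fraction` (defaults: nintedanib 1, pirfenidone
12/23), and the effect is then drawn from the matching side of 1 by
inverse-CDF on the truncated lognormal; replicate noise is
rejection-sampled (with a deterministic nudge as last resort) so the
*realised* median fold change always sits on the drawn side of 1 — the
specified fraction is therefore the true Bernoulli parameter, recoverable
within its exact binomial CI. A `responder_fraction` the effect
distribution cannot realise (no mass on the required side of 1) is an
error, never clamped.

FVC follow-up is generated so baseline ZOI% and FVC decline (baseline −
follow-up %FVC, in percentage points of predicted) correlate at
`zoi_dfvc_correlation` (default 0.80) via the standard
$r z + \sqrt{1-r^2}\,\varepsilon$ construction; decline has mean 5, SD 4
points, baseline %FVC is 65 ± 12 (ILD) — plausible values for a fibrotic
ILD clinic population, chosen once. A fraction 4/23 of ILD patients lose
follow-up (matching the emulated cohort's attrition); follow-up intervals
are 7.8 ± 1.3 months clipped to 6–12. Fibronectin DAB intensity and Col1a1
expression are linear in baseline ZOI% plus noise, with slopes anchored so
the two group means land on 0.075/0.122 (fibronectin) and 0.73/0.97
(Col1a1). A single master seed drives everything; each patient gets a
derived sub-seed, so any patient is reproducible in isolation.

What the generator does **not** emulate: real micrograph texture (uneven
illumination, debris, out-of-focus cells), spatial structure of invasion
(strands and sheets rather than independent blobs), non-normal ZOI%
distributions, informative loss to follow-up, and any biophysics of
migration. Passing recovery tests therefore demonstrate that the pipeline
is *internally correct* — it recovers what the generator planted — not
that the segmenter would match a human annotator on real images; for real
data the ROI-CSV path exists precisely so hand outlines can be scored by
the same downstream machinery.

## Statistical panel

`cohort_panel()` runs the cohort-level analyses on joined patient,
measurement, and response tables:

- **ILD vs control** baseline ZOI% (per-patient untreated medians) by
  Mann–Whitney, with mean ± SD summaries. The Mann–Whitney implementation
  uses midranks for ties, full enumeration of labelings when both groups
  have ≤ 8 observations and no ties, and the tie-corrected normal
  approximation otherwise (no continuity correction, so small normal-branch
  p-values are not floored).
- **Paired untreated vs treated** patient medians per drug by Wilcoxon
  signed-rank: zero differences dropped, exact sign enumeration for ≤ 12
  nonzero pairs, tie-corrected normal approximation beyond; an all-zero
  difference set reports p = 1 with a warning rather than failing.
  Parametric t tests can be run alongside, but the nonparametric tests are
  the defaults reported by the panel.
- **Simple linear regressions** (OLS; Pearson r; slope p from the t
  distribution on n − 2 df) of baseline ZOI% against FVC decline,
  fibronectin intensity, and Col1a1 expression, and of per-patient drug
  efficacy against baseline ZOI% and FVC decline. Efficacy ("ZOI ratio")
  is the per-patient **median fold change** — the same aggregate as the
  responder statistic, chosen for consistency since the aggregation was
  not pinned down externally. Constant predictors and n < 3 are reported
  as `degenerate`/`insufficient n`, never dropped silently. $R^2$ is
  identically $r^2$; printed values round half away from zero, the
  convention under which reported (r, R²) pairs are mutually consistent.
- **Response rates** overall, by diagnosis subgroup, and by progression
  label, each with exact Clopper–Pearson bounds; strata under 3 patients
  are flagged `insufficient n`.
- **Progression**: a patient with follow-up spirometry is a progressor
  when %FVC declines by ≥ 5 percentage points of predicted within 12
  months (boundary inclusive; "absolute" decline contrasting with decline
  relative to baseline, which `run_config(progressor_rule = "relative")`
  selects instead); missing follow-up is the label `undetermined`, not an
  error.

The FVC-decline orientation deserves a note: the panel regresses ZOI%
against *decline* (baseline − follow-up), the orientation in which
invasiveness and lung-function loss correlate positively; the patient
table stores the signed change `delta_fvc` (follow-up − baseline), so
decline is its negation.

## Problem sizes and tolerances in the test-suite

The suite exercises: exactness of disk-core recovery and noiseless-mask
segmentation; ZOI% recovery within 10% relative on 25 noisy synthetic
images (core radius 40 px, 200 cells, reach 60 px, noise SD 0.05, fixed
threshold 0.15 — chosen below the blob support cut and above the 3-sigma
noise floor); Jaccard ≥ 0.9 against truth masks; Clopper–Pearson
beta-quantile bounds against a binomial-tail root-finding oracle to 1e-9
for all k ≤ n ≤ 30; CI coverage over 2,000 binomial draws at n = 23,
p = 0.5 within [0.93, 0.985]; Mann–Whitney and Wilcoxon exact branches
against full enumeration on 200 randomized small-sample cases;
distributional recovery of the generator at 10,000 patients per group
(means within 2%, SDs within 5%); responder-fraction recovery at 1,000
patients within the exact CI; and correlation recovery (target 0.8,
n = 23) within [0.5, 0.95] over 100 seeds, the sampling band of r at that
n. These sizes keep the default test run to a few minutes while leaving
each check statistically meaningful.

## Known limitations

- The hull-based $H$ is only comparable to the union-based ground truth in
  dense invasion regimes; sparse scattered cells make the envelope much
  larger than the union, by design (that is what outlining an invasion
  front does).
- Core isolation absorbs cells merged with the core rim into $R$ when they
  cannot be morphologically distinguished from it; the residual bias is a
  few percent of $R$ in crowded rims.
- The generator's effect-size defaults are group-level summaries; per-
  patient fold-change distributions beyond those summaries are a modelling
  choice (lognormal), so synthetic cohorts match the emulated study's
  summaries and counts, not individual patients.
- Exact-test branches are enumeration-bounded (n ≤ 8 per group, ≤ 12
  nonzero pairs); beyond that the tie-corrected normal approximation is
  used, which at n = 23 floors the two-sided Wilcoxon p near 2.7e-5.
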