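---
title: "meioquant: models, estimators and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{meioquant: models, estimators and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the measurement
models, the estimators, the synthetic world they are validated against, and
the choices made where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. What is being measured

A live-imaged mouse oocyte going through meiosis I yields several
per-oocyte time series and one 3D trajectory set:

| stream | reporter | readout |
|---|---|---|
| `dextran` | 70 kDa dextran | nuclear-envelope permeabilization (NEBD onset) |
| `chromosome_volume` | H2B | chromosome condensation (thresholded 3D volume) |
| `pplk1_mtoc` | pT210 staining | kinase activation at MTOCs |
| `lamin` | lamin B1 | nuclear lamina disassembly |
| `spindle_aspect`, `spindle_volume` | MAP4 | bipolarization and spindle size |
| `securin`, `cyclin` | EGFP fusions | APC/C activity (degradation) |
| kinetochore tracks | CENP-C | congression, belt, alignment, tension |

All on-disk times are minutes since induction of meiotic resumption;
NEBD-relative times are derived columns. This single canonical axis avoids
the ambiguity of mixing absolute and NEBD-relative axes across figures.
Coordinates are µm in an arbitrary right-handed lab frame; every geometric
output is rigid-motion invariant (property-tested with random rotations
and translations).

## 2. Event detection on intensity traces

The core primitive, `detect_onset_end()`, implements the defined-threshold
rule: the onset is the first linearly interpolated crossing of `lo`
(default 0.1 of the normalized range) that stays beyond `lo` for at least
`sustain` frames (default 2); the end is the first crossing of `hi`
(default 0.9) thereafter. Falling signals are analyzed as `1 − value`, so
one routine serves both directions. The published analyses state only that
"defined thresholds" were used; the symmetric 10/90% convention is the
most common choice and reproduces the qualitative orderings of all
condition presets. Whether the original thresholds were absolute or
normalized is unstated; normalized fractions are assumed. A trace that
never crosses `lo` is a *no-event* result (not an error), and a trace that
crosses `lo` but never `hi` is an *open-ended* event; both carry flags and
are excluded from group means with reported exclusion counts.

### Noise handling

A naive first crossing through frame-to-frame noise is biased early by
roughly `noise SD / slope`, which at the default 2% noise and 1-min
sampling would shift condensation onsets by several minutes and break the
package's own recovery requirements. The pipeline wrappers
(`condensation_nebd_delay()`, `activation_onset()`,
`disassembly_duration()`) therefore precede threshold crossing with:

1. a centered moving average whose window is matched to each stream's
   transition speed (5 frames for the ~20 min dextran rise, 9 frames for
   the 45–75 min condensation, 9 for lamin, none for the 5-min-sampled
   kinase trace);
2. an isotonic (pool-adjacent-violators) projection onto the monotone
   transition shape, which guarantees a single crossing per level and
   removes first-passage dithering;
3. a two-pass normalization: a provisional min–max detection, then
   re-anchoring of the 0/1 levels at the medians of the plateau halves
   farthest from the transition. This removes the sensitivity of the
   thresholds to noise extremes and to sigmoid tails.

All three steps are exactly neutral on noiseless monotone traces, so the
closed-form examples and the noiseless closed loop (onsets recovered
within one sampling interval) are unaffected. With them, at default noise,
both onsets are recovered within 2 frames in well over 95% of simulated
control oocytes (tested at n = 200). `detect_onset_end()` itself applies
none of this — its arithmetic is pinned by exact unit tests and an
exhaustive-scan oracle — and `denoise = FALSE` disables it in the
wrappers.

NEBD onset is operationally defined as the dextran-influx onset `t1`
(permeabilization is the first step of nuclear envelope breakdown);
`delay = t2 − t1` is positive when condensation follows permeabilization.

## 3. Kinetochore-track geometry

Chromosome centers are kinetochore-pair midpoints (20 bivalents, 40
kinetochores). When pair labels are absent, `pair_homologs()` matches
kinetochores by minimizing total time-averaged pairwise distance over the
first five frames, using greedy nearest-pair selection plus 2-swap
refinement; because homologous kinetochores sit within ~1 µm of each other
while bivalents are several µm apart, this attains the minimum-cost
matching in the operating regime (verified against brute-force enumeration
for small sets, and 100% accurate on synthetic cohorts). An exact general
matching (blossom) was deliberately not implemented.

`estimate_axis_equator()` takes the centroid of the chromosome centers as
the equator point and the principal direction of least variance as the
spindle axis — for a belt or plate, the plane normal. The axis sign is
fixed deterministically (positive z, tie-broken by y then x). Collinear or
coincident centers raise degenerate-geometry errors. The original
equator-estimation algorithm is described only by citation; the
least-variance estimator is this package's design decision, not a claim of
identity.

Belt analysis projects the centers onto the equator plane per frame,
normalizes each radial distance by that frame's most distal chromosome,
and classifies membership strictly above 0.707. The belt-formation time is
the earliest frame at which the belt count attains its global maximum;
ties break to the earliest frame, and the scan starts 60 min after track
start because the axis is meaningless while the chromosomes are still a
dispersed ball (both config-exposed). Frames with fewer than three
chromosomes are flagged and excluded. Missing pair members are flagged,
never interpolated.

### Per-frame versus locked geometry

A single frame of 20 centers determines the axis only moderately well, and
after biorientation failure (PLK1 inhibition) the axial spread grows to
rival the belt radius, collapsing the eigen-gap — a late frame then no
longer determines the axis at all. The pipeline therefore measures:

- distances **at belt formation** with the per-frame estimate (the frame
  is well-conditioned there), and
- distances at later times against a **locked geometry**
  (`locked_geometry()`): the axis pooled over the best-conditioned of
  several windows after belt formation, and the equator point pooled over
  all post-belt frames. Pooling is justified because recordings are
  drift-registered (the synthetic data are drift-free by construction) and
  the spindle position is stationary on this time scale.

Even so, the locked axis carries a few degrees of error and the pooled
centroid a ~0.1–0.2 µm offset, so the *measured* maximum |axis position|
of a control cohort typically lands slightly above the true 8 µm
oscillation envelope (≈ 8.1 µm). The generator's true positions are
bounded at 8 µm exactly; the acceptance suite asserts the bound on the
true positions and reports the measured value as-is.

Spindle elongation is the first sustained crossing of the aspect-ratio
threshold 1.5 (config-exposed), and spindle volume is linearly
interpolated at 6 h post-NEBD.

## 4. Degradation kinetics

`normalize_cytoplasmic()` divides by the (interpolated) value at a
reference time, by default the first sample — the convention of
normalizing to 1 when imaging starts. `fit_degradation()` selects the
decline window automatically: from the last sample with `I_norm ≥ 0.9` to
the first subsequent sample within 0.1 of the smoothed minimum (both
config-exposed; the published line fit shows no window rule, so this is
the package's own), fits ordinary least squares, and reports
`D_rate = −slope` and `T_start` as the time the fitted line attains 1.0 by
extrapolation — even when the trace itself never reaches 1 after
normalization drift. A non-degrading trace yields `fit_valid = FALSE` with
`D_rate = 0`: a verdict, not an exception, because a flat reporter is the
central inhibited phenotype. `minimum_fraction()` takes the minimum of a
3-frame running median (robust to single-frame spikes; the published
minimum is stated only as approximate).

Outcomes are classified from the fit plus anaphase annotations
(segregation, polar body, decondensation — generator truth for synthetic
data, manual scoring for real data). One mapping choice: an oocyte with a
valid fit but no segregation is `partial_activation_no_anaphase`
regardless of how deep its minimum is, because the category list has no
separate class for full degradation without anaphase (a phenotype that
does occur after proteasome washout under PLK1 inhibition).

## 5. The synthetic world

`simulate_cohort()` draws each oocyte independently from its condition
preset; one sub-seed per oocyte makes cohorts bit-reproducible and
streams order-independent. Event times are Normal with the published
means and SDs (the distribution family is unstated in the source; Normal
is the default assumption). Key defaults that the source does not state,
chosen once:

| parameter | default | rationale |
|---|---|---|
| trace noise | 2% of dynamic range, additive Gaussian | small enough that parameter recovery dominates; config-exposed |
| sampling | 1 min resumption/lamin, 5 min kinase, 10 min tracks/spindle/degradation | typical confocal time-lapse intervals for these stream types |
| recording duration | 15 h | covers 12 h post-NEBD even for late-NEBD inhibited oocytes and lets slow degradation reach its plateau |
| dextran rise | 20 min (10→90%) | order of minutes, faster than condensation |
| condensation fall | 46 min control, 74 min inhibited | from the normalization anchors of the published kinetics |
| belt ring radius | 11 ± 0.3 µm | prometaphase belt at the periphery of a ~25 µm spindle |
| OU relaxation time | 20 min | chromosome oscillation time scale |
| biorientation lag | 20 min | alignment starts a short dwell after the belt |
| alignment tightening | 45 min (exponential) | alignment established within the first hour |
| inter-KT distance | 0.9 ± 0.08 µm control, 0.6 ± 0.08 µm inhibited | reduced tension under inhibition; absolute values are package defaults |
| reporter re-accumulation | +0.03/h after anaphase | reporter synthesis continues in meiosis II; keeps the trace minimum localized |

Generators are built so the *detectors* recover the drawn parameters
exactly on noiseless data: sigmoids cross 10% of their range exactly at
the drawn onset; the aspect ratio crosses 1.5 exactly at the drawn
elongation time; degradation is piecewise-linear because the estimator is
a line fit (curvature misspecification is deliberately excluded from the
defaults and available via overrides).

### Axial dynamics and calibration

Chromosome centers congress radially from a dispersed ball (radius 5 µm)
to the belt ring, with per-chromosome membership-crossing times staggered
so the belt count first reaches its maximum exactly at the drawn
`t_belt`; belt angles are near-evenly spaced (as in real plates), which
keeps the projected centroid at the ring center. Along the axis, centers
follow an Ornstein–Uhlenbeck process reflected at the condition's
excursion bound (8 µm control, 16 µm inhibited), whose marginal SD tracks
a schedule exactly (deterministic state rescaling): dispersed-ball SD →
belt SD → late SD.

The published mean chromosome–equator distances are *measured* values —
distances to an equator estimated from the same 20 centers — and that
estimator absorbs part of the axial spread. The generator therefore
calibrates the true axial SD at belt formation against the measurement
operator itself, by a fixed internal Monte-Carlo with common random
numbers (`calibrate_axial_sigma()`); the late SD uses the plain
truncated-normal inversion because the locked-geometry operator is nearly
unbiased. This is a forward calibration of the stated world, fixed before
any acceptance evaluation, not a per-seed adjustment.

One stated design idea was not followed: pole-ward excursions under PLK1
inhibition as a separate Poisson-event process. A separate excursion
process would break the exact correspondence between the stated mean
distances and the marginal law of the axial process; the reflected OU with
a larger late SD and a 16 µm bound reproduces the phenotype (excursions up
to the bound) while keeping the calibration closed-form testable.

### What a green test does and does not establish

The generator reproduces the *statistical structure* of each condition —
event-time distributions, trace shapes, belt formation, alignment spread,
degradation kinetics, phenotype fractions — with independent oocytes,
stationary spindles, Gaussian noise and no optical artifacts. It does not
emulate mechanistic biophysics (microtubule dynamics, SAC signaling),
photobleaching, drift, segmentation failures, or oocyte death. A green
closed-loop test therefore establishes that the estimators are correct and
calibrated for data with this structure; it cannot certify performance on
pathologies the world does not contain.

## 6. Rendering and image quantification

`render_scene()` builds three-channel voxel stacks: chromatin as a union
of spherical blobs whose total volume follows the chromosome-volume trace,
dextran as uniform cytoplasm plus a nuclear sphere at the trace's influx
fraction, and kinetochore/MTOC foci as Gaussian spots; Gaussian PSF,
Poisson shot noise and Gaussian read noise are optional. Chromatin
segmentation thresholds per time point (Otsu by default — the published
method states only "intensity-thresholded"; a fixed threshold exists for
exact tests), labels 26-connected components (the most inclusive standard;
connectivity is unstated in the source) and reports the total
above-threshold volume. Nuclear dextran is measured on the single
z-section through the nucleus center (faithful to the published 2D
measurement; a 3D spherical variant is provided but non-default). Spot
detection takes 26-neighborhood maxima above a floor, merges within a
minimum separation (brightest wins) and refines to intensity-weighted
centroids, sorted by z, y, x. Fold enrichment is the ratio of
spherical-probe means at target versus reference points.

Stacks are written as minimal little-endian uncompressed 32-bit-float
multi-page TIFFs with a JSON description carrying axis sizes and voxel
dimensions — a codec the package carries itself because no TIFF-capable R
package is available in the target environment; it reads only the dialect
it writes.

## 7. Statistics

Group comparisons use Welch's unequal-variance t test by default (the
source does not name its test; results should be read as directionally
comparable, not test-identical), with a Mann–Whitney option for
heavy-tailed metrics such as equator distances under inhibition. Two
zero-variance groups with equal means give p = 1 by convention. No
multiple-testing correction is applied by default (per-contrast p values);
Holm is available in `stats::p.adjust` form downstream. Summaries report
n, mean, SD, 95% CI and exclusion counts per condition and metric;
single-oocyte groups are flagged rather than given an SD.

## 8. Known limitations

- Cohort sizes of the published experiments are small (3–17 oocytes), so
  cohort means fluctuate by design; recovery targets are only meaningful
  within ~2 standard errors of the preset.
- The measured maximum axis excursion slightly exceeds the true envelope
  (estimator noise; see §3).
- The belt-formation time is quantized to the 10-min track sampling and
  detected on average ~5–10 min late.
- The trace-noise model is white; temporally correlated noise would
  degrade onset detection and is not part of the default world.
- `read_stack()` supports only the package's own TIFF dialect.
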