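---
title: "Behavioral profiling of zebrafish larval drug screens: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioral profiling of zebrafish larval drug screens: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvascreen)
```

# Overview

`larvascreen` implements a complete analysis pipeline for high-throughput
behavioral drug screening with 5-dpf zebrafish larvae imaged in a 384-well
(four 96-well plate) format:

1. **Protocol** — the 3-h, 18-period stimulus schedule (moving colored
   lines, acoustic pulse trains) and the mapping of video frames to
   periods and active stimuli.
2. **Synthetic data** — a parametric generator of per-well larval
   movement/location time series with known ground truth, and a renderer
   that turns tracks into plate-image sequences.
3. **Tracking** — frame-differencing image analysis: channel selection,
   thresholded difference masks, per-well area/centroid measurement,
   movement calls, and the "upper half" location state.
4. **Metrics** — per-period activity and location summaries, automatic
   low-movement exclusions, and the ten behavioral outcome measures.
5. **Screening statistics** — treatment-vs-vehicle behavioral profiles,
   Welch's test with tiered Bonferroni correction, color-coded profile
   tables.
6. **Clustering** — complete-linkage hierarchical clustering of profiles
   under a weighted squared-Euclidean distance with down-weighted
   optomotor features, additive-inverse hypothetical profiles, cluster
   cohesion scores, and CDT/GTR export for tree-viewer programs.

This vignette records the models, the tunable parameters, the numerical
conventions, and the design decisions behind each stage — and, just as
importantly, what the synthetic data do *not* emulate.

# The assay and its schedule

A camera photographs four 96-well plates every 6 s for 3 h (1800 frames);
a projector below the glass stage shows a light-gray background
(RGB 210,210,210) and the visual stimuli; two speakers deliver acoustic
pulses. The recording divides into eighteen 10-min periods:

| Periods | Stimulus |
|---|---|
| 1–6 | none (baseline hour) |
| 7–8 | red lines (255,0,0) moving down, then up |
| 9–10 | green lines (0,180,0) down, up |
| 11–12 | blue lines (0,0,230) down, up |
| 13–14 | red lines at 16× speed (7 mm per 0.5 s vs 7 mm per 8 s) down, up |
| 15 | none (rest) |
| 16 | acoustic pulses (100 ms, 400 Hz) at 20-s intervals |
| 17 | acoustic pulses at 1-s intervals |
| 18 | acoustic pulses at 20-s intervals |

Lines are 1 mm thick and 7 mm apart. Frames are 0-based; periods are
1-based so that "period 15/16/17" reads exactly as in the assay's
nomenclature. Period length in frames is derived as
`600 / frame_interval_s`, so a reduced schedule
(`default_schedule(frame_interval_s = 60)`, 10 frames per period) keeps
the full 18-period structure while running fast; the test-suite
property checks use this reduced scale unless the full scale is the
point of the test.

Individual acoustic pulses are sub-frame events at the 6-s sampling
interval (a 1-s pulse train delivers six pulses between consecutive
frames). The package therefore models acoustic blocks as period-level
elevations of movement probability rather than per-pulse events — the
outcome measures never resolve individual pulses either.

# The synthetic behavior model

The generator is deliberately a **linear-probability model**, not a
mechanistic swim model: every activity-family outcome measure then has a
closed-form expectation, which makes parameter recovery a sharp test of
the whole pipeline.

Each larva is a `phenotype()` with parameters (all per frame):

* `p_move_base` — baseline movement probability (default 0.2; the
  vehicle-control graphs of this assay family put baseline activity in
  the 10–25% band, and no exact number is published, so 20% is the
  package's fixed choice of a realistic baseline),
* `startle_gain` — added during 20-s-interval acoustic periods,
* `excitability_gain` — added on top of the startle gain during the
  1-s-interval period,
* `habituation_drop` — subtracted during the second half of the
  1-s-interval period (a step drop, mirroring the definition of the
  habituation statistic as first-half minus second-half activity; a
  continuous exponential decay would not be identifiable from that
  statistic),
* `omr_gain[class]` ∈ [−1, 1] — optomotor coupling per stimulus class.

Per frame the movement probability is clipped to [0, 1]. On movement the
larva takes a step with independent horizontal and vertical components;
magnitudes are uniform in `step_mm` (default 0.5–3.5 mm, the scale of
single swim bouts over a 6-s interval), the horizontal sign is
symmetric, and the vertical sign is up with probability
`(1 + b) / 2`, where `b = omr_gain[class] × (+1 if lines move up, −1 if
down)` during visual periods and 0 otherwise. Positions reflect at a
containment circle of radius `well radius − margin_mm` (default margin
0.5 mm, half the body width: a real larva's centroid cannot lie on the
wall). The reflection is a radial fold — the heading is kept and the
radius reflects at the boundary.

## Expected values and OMR calibration

With `h = habituation_drop`, the closed forms are (in percent /
percentage points):

* `1h = P15 = 100 · p_move_base`
* `S = 100 · startle_gain`
* `Hab = 100 · h`
* `E = 100 · (excitability_gain − h/2)` — the 1-s-interval period's mean
  activity includes the drop in its second half, and excitability is the
  period-17-minus-period-16 difference, hence the `−h/2` term.

The optomotor measures have no closed form: they are occupancy
statistics of a reflected, biased random walk, which also carries
position memory across period boundaries (a few movement events'
worth). `expected_vector()` therefore evaluates them with a registered
Monte-Carlo oracle (`expected_omr_mc()`), and `calibrate_omr_gain()`
inverts the monotone gain→response curve (Monte-Carlo evaluation on a
gain grid, `cummax` to suppress jitter, linear interpolation) so that
fixtures can be programmed in percentage points. The response is
roughly linear at ≈ 0.9–1 pp per 0.01 gain under the defaults.

## Determinism

Every well's track is reproduced bit-for-bit from
`(phenotype, schedule, geometry, seed)`. Screen simulations derive
per-well seeds by a stable multiplicative-congruential hash of
`(master seed, plate, well index)` — exact in double arithmetic and
independent of iteration order. All randomness flows through R's RNG
(`set.seed`); the compiled walk consumes pre-drawn uniforms.

## What the generator does *not* emulate

No circadian or slow drift in activity; no larval growth, death, or
edge preference (thigmotaxis); no correlation between movement bouts
beyond the positional memory of the walk; no per-session or per-plate
batch effects; movement is binary per frame with no bout-length
structure. Passing tests therefore validate the *analysis machinery* —
counting, exclusions, statistics, clustering — under known ground
truth, not the biological realism of any particular effect size.

# Rendering and tracking

The renderer draws, per frame: the projected background (210,210,210),
the active period's lines at their scheduled phase, and each larva as a
dark horizontal ellipse (4 × 1 mm at intensity 60). Two deliberate
conventions:

* **Camera-response emulation.** The physical assay matches camera
  exposure so stimuli nearly vanish in the analysis channel. Nominal
  red (255) on the 210 background would leave a difference of 45 —
  above the threshold of 40 — so rendered lines are clamped to within
  30 intensity units of the background in their selected channel (red
  renders at 240; green 180 and blue 230 already qualify). Channel
  *selection* still uses the nominal stimulus colors.
* **Stroboscopic fast red.** The 16×-speed lines advance exactly
  84 mm = 12 line spacings per 6-s frame, so they alias to a static
  pattern at the sampling rate. This is irrelevant to the analysis
  (lines are invisible in the selected channel either way).

Tracking re-implements the frame-differencing analysis:

* **Channel selection** minimizes |stimulus − background| per channel
  (ties → lowest index), re-evaluated at each period boundary.
* **Difference mask**: `|curr − prev| ≥ 40` by default, threshold
  inclusive. The absolute difference detects both the vacated and the
  newly occupied position; an image-processing environment that clamps
  negative differences sees only the newly darkened half, and
  `difference_mask(mode = "onesided")` reproduces that behavior.
* **Movement call**: changed area within the well ROI ≥ `min_area_px`
  (default 3 px; the original threshold is unpublished, so this is a
  configurable choice).
* **Location**: after each movement the larva is "up" if its centroid
  row is strictly above the well's horizontal midline (a centroid
  exactly on the boundary counts as lower half); the state carries
  forward between movements and is undefined before the first movement.
  The centroid itself is measured, by default, on the dark body pixels
  of the current frame within the ROI (`centroid_mode = "body"`): the
  one-sided difference component equals the new position only when the
  displacement exceeds the body size, whereas the body pixels give the
  position within half a pixel regardless of overlap. The
  `"dark"`/`"mask"` modes retain the pure difference-based variants.
* **Bookkeeping**: one observation row per well per frame *pair* —
  wells × (frames − 1) rows, since the first image has no predecessor.
  A full recording is conventionally described as 384 × 1800 rows; the
  metrics stage accepts either bookkeeping and computes fractions over
  the frames actually present.

On rendered fixtures, movement-call agreement with ground truth
exceeds 99% and centroid error stays below 1 px for larvae whose body
lies fully inside the circular ROI. Edge-clipped bodies (the renderer
has no well walls) shift the measurable centroid; this is a renderer
limitation, not a tracker one.

# Outcome measures and exclusions

Per period: `% move` = percentage of frames with movement; `% up` =
percentage of time the "up" state is true, over frames where the state
is defined (carry-forward time weighting; an events-only variant that
averages over movement frames is available as `up_weight = "event"`).
The 1-s-interval period splits into halves for the habituation
statistic; odd frame counts give the first half the extra frame.

Exclusions, applied before any statistic: larvae moving < 1% of the
recording are excluded entirely; a larva moving < 5% of a 10-min period
is excluded from optomotor measurements *during that period* only —
per-measure, never propagated to the activity measures.

The ten measures (percent / percentage points): `1h` (mean activity,
periods 1–6), `P15` (activity, period 15), `Hab` (first − second half
of period 17), `S` (period 16 − period 15), `E` (period 17 − period
16), `R/G/B/FR` (per-class OMR: `% up` in the up-moving minus the
down-moving period), and `RGB` (combined OMR). The original templates
do not state how `RGB` pools; the default is the unweighted mean of the
defined per-class OMRs (stays in pp, degrades gracefully when some
classes are excluded), with a pooled location comparison across all
visual periods (`omr_combined = "pooled"`) as the alternative.

# Screening statistics

Per-larva values are the statistical unit (matching the large-n design;
session/batch effects are out of scope). Profiles are treatment-group
means minus vehicle-control means, in percentage points, with two-sided
Welch tests per behavior. Degenerate cases return `p = 1` with a
warning (two zero-variance samples with equal means, or n < 2) rather
than failing — synthetic edge cases must not crash a screen; two
zero-variance samples with *different* means return `p = 0`.

Bonferroni tiers are `alpha / m` for alpha ∈ {0.05, 0.01, 0.001}: the
190-drug screen tests at 2.6 × 10⁻⁴ / 5.3 × 10⁻⁵ / 5.3 × 10⁻⁶, an
11-drug validation at 4.5 × 10⁻³ / 9.1 × 10⁻⁴ / 9.1 × 10⁻⁵, a 3-dose
series at 0.017 / 3.3 × 10⁻³ / 3.3 × 10⁻⁴. Displayed values round to 2
significant figures; comparisons always use unrounded thresholds.

Profile tables color percentage-point differences on a diverging scale
clipped at ±25 pp: green → white → red for screen-style tables, green →
black → red for cluster-style displays.

## Calibration at reduced scale

The null-calibration property (200 simulated no-effect screens of 190
groups) runs at n = 12 per group — control included — with 10 frames
per period. At these sizes the per-comparison rejection rate at
0.05/190 tracks the nominal level closely, with a mild conservative
tendency: the t reference distribution is exact only for normal data,
and bounded, coarsely discretized percentages at n = 12 carry slightly
less mass at the ~4.5-sigma two-sided tail than t does. False-positive
control therefore holds with a little to spare. A caveat
worth knowing: with a *very unequal* design (a vehicle control an order
of magnitude larger than each treated group, as in the full-scale
screen), Welch's test becomes anti-conservative in the extreme tail on
bounded, skewed percentage data — the far-tail rate can exceed nominal
severalfold at small treatment n. This is a property of the t
approximation, not of this implementation; it argues for caution when
interpreting borderline far-tail p-values from small groups against a
large control at coarse temporal resolution.

# Clustering of behavioral profiles

Distances follow the convention of the clustering tool the assay's
profiles were designed for: the weight-normalized **mean squared
difference** `d = Σ wᵢ(xᵢ−yᵢ)² / Σ wᵢ` over mutually defined features,
*without* a square root (a `sqrt` flag provides the textbook metric;
merge order is identical). Missing values are handled pairwise with
weight renormalization. The five optomotor features carry weight 0.5
("Eweight"), the five activity features weight 1 — the optomotor
responses are noisier and would otherwise dominate the squared
distances. No centering, scaling, or transformation is applied before
clustering (asserted by test): the distance is meant to compare raw
effect magnitudes.

`complete_linkage()` is a hand-written naive agglomeration with a
deterministic tie-break (the cluster pair containing the smallest
original row indices merges first), so merge sequences are reproducible
and row-order-independent; `stats::hclust` serves as an independent
cross-check in the test suite, never as the implementation. Triangle
inequality is *not* claimed for the no-sqrt distance; only symmetry,
non-negativity and identity are.

The additive inverse of a reference profile (every defined delta
negated, `-inv` label suffix) acts as a hypothetical compound with
opposite neural effects; finding real drugs that cluster with an
inverse is the package's search mechanism for opposite-acting
compounds, and the packaged fixture families demonstrate it: the
inverse of an "INDY-like" profile lands in the "CsA-like" cluster and
vice versa.

Cluster **cohesion** is reported as the mean pairwise Pearson
correlation over members' mutually defined features (minimum pairwise
correlation available as an alternative). The tree-based reports of the
original analysis print per-cluster "correlation" values without
stating a formula; cohesion here is a clearly labeled reconstruction,
not that formula.

CDT/GTR export writes the clustered data table (GID/UNIQID/NAME/
GWEIGHT columns, EWEIGHT row carrying the feature weights, rows in leaf
order) and the gene-tree file (one node per merge; scores are negated
merge heights so larger = tighter, as tree viewers expect). `read_cdt()`
inverts the CDT for round-trip checks.

# Fixture families

`reference_profiles()` packages two noise-perturbed profile families
with the qualitative signature of the calcineurin-axis compound
classes: "CsA-like" (increased early and rest activity, increased
excitability, decreased optomotor responses) at magnitudes of 10–18 pp,
and "INDY-like" as its elementwise negation. Magnitudes are fixture
parameters on the scale of validated drug effects, not measured ground
truth; per-component Gaussian noise defaults to 3 pp.

# Problem sizes used by the tests

The property suites choose sizes that make each check sharp:
oracle-equivalence sweeps run 1000 random instances per operation at 10
frames per period; parameter recovery runs 100 replicates of a
160-vs-160 experiment at the full 1800-frame schedule (tolerances ±3 pp
for the activity family, ±5 pp for the optomotor family, flagging at
the 11-comparison tier); null calibration runs 200 screens × 190 groups
× 10 behaviors at n = 12 and 10 frames per period; the tracking
round-trip renders one 96-well plate at 6 px/mm for 100 frames
spanning a baseline/visual-period boundary. The acceptance script
(`scripts/acceptance.R`) re-runs scaled versions of the same
computations from scratch.

# Known limitations

* The OMR expectation is Monte-Carlo, not closed form; calibrated
  gains carry ≈ 1 pp of calibration error under the default settings.
* Between-period position memory slightly couples adjacent optomotor
  periods (visible as sub-pp biases at full scale, a few pp at the
  10-frames-per-period reduced scale).
* One larva per well; no identity maintenance, no multi-animal wells.
* The renderer draws no well walls, so bodies can be clipped by the
  circular ROI near the edge (affects centroid accuracy there, not
  movement calls).
* Far-tail Welch calibration under very unequal group sizes (see
  above).
* Quantitative drug-specific effect sizes from the original recordings
  are out of scope; the supplementary per-drug datasets can be ingested
  as vector tables but are not required by any computation here.
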