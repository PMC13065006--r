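---
title: "Centre-of-mass energetics and fatigue: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centre-of-mass energetics and fatigue: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tenniswork)
```

## The question the package addresses

On-court workload monitoring in tennis lacks an established, non-invasive
metric. Mechanical work — the energy a player puts into accelerating and
raising the body — is a candidate: it can be computed from whole-body
kinematics captured by a markerless multi-camera system, without any
wearable. `tenniswork` implements the full analysis chain that connects
mechanical work accumulated during a fatiguing on-court protocol to acute
neuromuscular fatigue, operationalised as the decline in peak forward
centre-of-mass (CoM) velocity during maximal sprints.

The protocol the package models: a cycle is three sets, each a serve
followed by eight alternating groundstrokes at a metronome cadence (one
ball every 2.0 s for men, 2.5 s for women), with the third set ending in a
maximal sprint to the net. Cycles repeat until volitional exhaustion. Only
the third set of each cycle is captured (30 s at 200 Hz), and cycle work
is taken as three times the captured groundstroke-section work plus the
sprint work — the three sets of a cycle are assumed interchangeable, so
any within-cycle variability is not represented.

## Mechanical work model

Work is computed from energy time series by increment/decrement
bookkeeping, in the tradition of CoM energetics for locomotion:

* **External work.** The CoM's kinetic energy `0.5 |v|^2` plus potential
  energy `g h` (per kilogram of body mass) is summed into one total energy
  series. Summing its positive increments over a trial section gives
  positive external work `w_ext_pos`; the negative increments give
  `w_ext_neg`. The telescoping identity
  `w_pos + w_neg = E_end − E_start` holds exactly and is asserted
  throughout the test suite.
* **Internal work.** For each of 14 body segments, translational plus
  rotational kinetic energy relative to the CoM
  (`0.5 m |v_rel|^2 + 0.5 ω' I ω`, mass-normalised) is computed from
  de Leva-style inertial parameters scaled to the subject. Segment
  energies are summed within three limb groups — bilateral legs, bilateral
  arms, trunk — increments are taken per limb group, and the limb works
  are summed. Summing energies *within* a limb before taking increments
  allows energy exchange between segments of a limb but not between
  limbs; this is one of two defensible readings of limb-level bookkeeping
  and is fixed here as the package's convention.
* **Total work** is external plus internal, enforced on construction of
  every work summary.
* **Units.** All energies and works are J/kg (Table-style reporting per
  kilogram of body mass); multiply by body mass for Joules. `g` is
  9.81 m/s².

### CoM proxies

Two cheaper surrogates for the CoM are carried through the identical
energy-to-work path:

* the **pelvis point** — a fixed anatomical point, standing in for any
  mid-hip-style track; and
* the **bounding-box pseudo-CoM** — per camera, the centre of the 2D box
  around the projected body; the per-frame box centres are back-projected
  and intersected in 3D by least squares, then low-pass filtered.

Both carry extra motion that the true CoM does not have (limb extension
changes a bounding box; the pelvis rocks relative to the CoM). A
superimposed oscillation of amplitude `A` with `k` periods adds
approximately `2Ak` of positive work to an energy series — each period
contributes one rise of `2A` — so proxy work systematically
*overestimates* CoM work. This mechanism is verified in closed form in
the tests and drives the repeated-measures Bland–Altman comparison in the
pipeline.

## Signal processing

* **Filtering.** Zero-lag (forward–backward) Butterworth low-pass at 6 Hz.
  "4th order" names the effective order after both passes (design order 2
  per direction), the common biomechanics convention; `order_convention =
  "per_pass"` selects the other reading. Edges are padded with 1 s of
  mirror (even) reflection: point reflection was rejected because an
  oscillatory end value creates a DC pedestal in the pad whose step rings
  inside the retained region on the backward pass.
* **Cut-off selection.** A Winter-style residual analysis is available:
  RMS residual between raw and filtered series per candidate cut-off, a
  straight line fitted to the noise-dominated upper half of the candidate
  range, and the smallest candidate whose residual does not exceed the
  line's intercept (plus 1% of the worst-candidate residual, which
  absorbs the gradual roll-off of a finite-order filter on noiseless
  signals). Residuals are measured with 1 s trimmed from each end so edge
  transients do not inflate the noise estimate. The pipeline default is
  the fixed 6 Hz cut-off.
* **Differentiation.** Central differences (exact for linear signals,
  second-order otherwise), one-sided at the series ends. Velocities are
  always computed *after* position filtering.

## Trial segmentation

Working in a court frame (x along the baseline, y forward toward the net,
z up, origin at the baseline centre):

* **Serve start** — the second local minimum counting backwards from the
  most prominent peak of vertical CoM position (the countermovement dip
  before the upward drive). Prominence is topographic; ties go to the
  earlier peak.
* **Transition** (groundstrokes to sprint) — the change of direction: a
  local minimum of resultant CoM speed before the rise to the sprint's
  peak speed. Two robustness choices: only minima whose depth is at least
  20% of the window's speed range qualify (shallow dips on the
  accelerating flank are not direction changes), and the search runs on a
  3 Hz zero-lag re-smoothed speed trace, since the change of direction is
  a ~1 Hz feature and residual observation noise otherwise shifts the
  argmin across the flat valley floor. Among qualifying minima the
  slowest point is taken.
* **Sprint end** — the first sample with forward CoM position at or
  beyond 8.5 m from the baseline (no interpolation; work integration ends
  at that sample). An unreached threshold is an explicit
  incomplete-sprint error.
* **Fatigue measure** — peak forward CoM velocity between transition and
  sprint end, expressed per cycle as a percentage of the player's overall
  maximum (baseline sprint included).

## Proxy reconstruction geometry

Cameras are ideal pinholes (no lens distortion — a documented
simplification; the synthetic rig is distortion-free by construction).
Rays through observed pixels are intersected by minimising the summed
squared perpendicular distances, a closed-form 3×3 linear solve. One
outlier pass drops cameras whose ray-to-point distance exceeds 0.15 m
(configurable) and re-solves once; the iteration count and threshold are
package choices, as only the objective — least-squares intersection with
outlier discarding — is fixed by the method. Degenerate geometry (fewer
than two usable rays, near-parallel rays) errors out rather than
returning a point.

## Statistics

* **Per-player association.** Pearson correlation between per-cycle peak
  sprint velocity (% of maximum) and cumulative positive work of a chosen
  variant (total, external, pelvis, bounding box). Negative-work variants
  are near-duplicates of the positive ones and are off by default,
  available behind `include_negative`.
* **Pooling.** Random-effects aggregation on the Fisher-z scale: each r
  is transformed with sampling variance `1/(n−3)`, between-player
  variance `tau²` estimated by the DerSimonian–Laird moment estimator
  (truncated at zero), pooled with weights `1/(1/(n_i−3) + tau²)`, and
  the estimate with its 95% CI back-transformed through `tanh`. Players
  need more than 3 cycles to contribute. A single player degenerates to
  that player's r with its large-sample CI.
* **Magnitude labels.** |r| strictly above 0.5 / 0.7 / 0.9 is large /
  very large / extremely large; boundary values fall below the label.
* **Agreement.** Repeated-measures Bland–Altman with the true value
  varying between trials: per-pair differences (proxy − CoM) are
  decomposed by one-way random-effects ANOVA over players into within-
  and between-player components (unequal trial counts via the standard
  `n0` coefficient), and the 95% limits of agreement are
  `bias ± 1.96 √(sd_within² + sd_between²)`. The variance-components
  route was chosen over the subject-mean route because work genuinely
  differs across cycles.
* **Design sensitivity.** `min_detectable_r(n, alpha, power)` inverts the
  two-sided Fisher-z power equation
  `atanh(r) √(n−3) = z_{1−α/2} + z_power` in closed form. For n = 15,
  α = 0.05, power = 0.8 it gives r ≈ 0.669. This documents the package's
  own formula; power software with unstated settings can report other
  values for the same inputs.

## The synthetic cohort generator

No motion-capture data ships with the package; a seeded kinematic
generator stands in for it, so every downstream stage is testable. It is
kinematic, not dynamic — splined waypoints and sinusoids, no
ground-reaction or muscle model — which suffices because everything
downstream consumes kinematics only.

Per 30-s trial at 200 Hz: a serve with a two-dip countermovement before
the most prominent vertical peak; eight alternating lateral groundstroke
excursions at the configured cadence; a run back along the baseline into
a change of direction; and a forward sprint whose position follows a
logistic curve, placing its configured peak velocity at the midpoint and
crossing 8.5 m before the capture ends. Segment motion is superimposed
oscillation around the CoM with one base phase per limb chain, fixed
proximal-to-distal lags, roughly antiphase bilateral coordination with
jitter, and a stronger racket arm; amplitudes are scaled so that internal
work lands near one third of total, matching the observed share in this
kind of protocol. A player's stroke style (phases, frequency jitter) is
drawn once per player — coordination is a stable personal characteristic
— which also makes the noise-free limit of the analysis exact. The
pelvis proxy adds a slow offset plus a high-frequency (3.5 Hz, 2.5 cm
before scaling) component; the bounding-box stream is generated by
projecting body keypoints into an 8-camera surround rig and taking
per-view box centres (no racket in the keypoint set).

Fatigue is linear: the peak velocity of cycle c is
`baseline − slope × W_cum(1..c) + noise`, with baselines drawn at
6.0 ± 0.5 m/s, log-normal per-player slopes (mean 6.5e-4 m/s per J/kg),
and a 0.15 m/s trial-to-trial noise SD — roughly 2.5% of peak velocity,
a realistic repeatability for sprint peaks. Cumulative work includes the
current cycle, whose strokes precede its closing sprint; because a
cycle's work depends weakly on the prescribed velocity, the generator
refines the velocity once against the cycle's own work (fixed-point
residual below 1e-4 m/s). Players stop once modelled velocity falls below
80% of baseline (volitional exhaustion), within a 4–12 cycle range.
Under these defaults a 15-player cohort completes cycles in the
mid-single digits with velocity reductions around 20%, and pooled
correlations in the low −0.9s — the qualitative regime the analysis is
designed for.

What the generator does *not* emulate: pose-estimation artefacts
(occlusion, identity switches, keypoint jitter structure), lens
distortion, racket effects on the bounding box, set-to-set variability
within a cycle, and non-linear fatigue dynamics (an exhausted player's
plateau). Tests passing on generator output therefore demonstrate the
correctness and robustness of the *analysis* under controlled, realistic
kinematics — not performance on real markerless data.

## Numerical choices and degenerate inputs

* Work bookkeeping is exact summation of first differences; no
  integration scheme is involved, so the telescoping identity is exact.
* The noise-free limit of the pipeline gives per-player r = −1 to float
  precision for the total-work variant (velocity is an exact linear
  function of cumulative total work). External and proxy variants are
  smooth but non-affine functions of sprint velocity, so their
  deterministic-limit correlations sit at −1 within about 5e-5 — an
  intrinsic property of any physical generator, not an approximation
  error.
* Trials that fail segmentation are excluded with a named reason; a run
  fails outright if more than 20% of trials are excluded.
* Missing proxy trajectories yield `NA` work fields, never silent zeros.
* All randomness flows from a single seed through per-player and
  per-trial substreams; rerunning a pipeline with the same seed
  reproduces every CSV and JSON byte-identically.

## Test and simulation sizes

The shipped tests exercise the full pipeline at sizes chosen to keep the
suite fast while preserving the cohort structure: event detection on 100
single trials, estimator recovery on 500 stats-level replicates,
noise-free and determinism checks on 2–4-player cohorts at 4 cycles each,
and the demo analysis in `scripts/acceptance.R` on the full 15-player
default cohort.

## Known limitations

* Products of inertia are neglected (principal radii only), matching the
  published segment tables.
* The merged head+trunk segment's CoM and gyration fractions are derived
  values, since published tables split the trunk into three parts.
* The exclusion rule for unsegmentable trials and the single-pass outlier
  rejection are package choices where the method leaves the procedure
  unspecified.
* `read_trial`/`write_trial` cover the package's own trajectory CSV
  dialect; no OpenSim `.mot`/`.sto` ingestion.
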