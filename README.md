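# tenniswork

Mechanical work as a workload-monitoring metric in tennis: this package
computes whole-body centre-of-mass (CoM) energetics from motion-capture
kinematics of an on-court fatiguing protocol and relates the accumulated
work to acute neuromuscular fatigue. It is written for sports
biomechanists and performance scientists who want a tested, reproducible
implementation of the full chain — energetics, event detection,
proxy reconstruction, and the repeated-measures statistics — plus a
seeded synthetic cohort generator so everything runs without any data
download.

## The model in brief

For a trial section, **external work** is the sum of positive (or
negative) increments of the CoM's mass-normalised mechanical energy

```
E(t) = ½|v(t)|² + g·h(t)        [J·kg⁻¹]
w_pos = Σ max(ΔE, 0),   w_neg = Σ min(ΔE, 0)
```

**Internal work** sums, within each limb group (bilateral legs, bilateral
arms, trunk), the segments' kinetic energy relative to the CoM,
`½m|v_rel|² + ½ωᵀIω` with de Leva-scaled segment inertias, then takes
increments per limb and adds the limbs. **Total** = external + internal.
A protocol cycle's work is three times the captured groundstroke-section
work plus the sprint work. Two CoM proxies — the pelvis point and a
pseudo-CoM triangulated from multi-camera bounding-box centres by
least-squares ray intersection — go through the identical path, and
systematically overestimate external work because their extra
oscillatory motion adds ≈ 2·A·k of positive work per superimposed
oscillation of amplitude A and k periods.

Fatigue is measured as the per-cycle peak forward sprint velocity (% of
the player's maximum) and related to cumulative positive work by
per-player Pearson correlations pooled on the Fisher-z scale with
DerSimonian–Laird random effects; proxy agreement uses repeated-measures
Bland–Altman (variance components over players).

## Worked example

Simulate one protocol trial (serve, eight groundstrokes, sprint) for a
77.2 kg male player with a 6.0 m/s target sprint peak, then run the
single-trial pipeline — filter, segment, compute work:

```r
library(tenniswork)
player <- list(id = "P01", sex = "male", body_mass = 77.2, height = 1.82,
               segment_lengths = default_segment_lengths(1.82))
sim <- simulate_trial(player, cycle_index = 1, v_peak = 6.0, seed = 42)
res <- process_trial(sim$trial)
cat("peak sprint velocity:", round(res$peak_velocity, 2), "m/s\n")
round(as.data.frame(res$cycle)[, c("w_ext_pos", "w_int_pos", "w_tot_pos",
                                   "w_pelvis_pos", "w_bb_pos")], 1)
```

```
peak sprint velocity: 6.02 m/s
  w_ext_pos w_int_pos w_tot_pos w_pelvis_pos w_bb_pos
1     244.3     100.3     344.6        357.8    593.5
```

Reading the output: the detected sprint peak (6.02 m/s) recovers the
prescribed 6.0 m/s through filtering and differentiation. Per protocol
cycle the player does 244 J/kg of positive external work and 100 J/kg of
internal work (≈ 29% of the 345 J/kg total — internal work is roughly a
third). Both proxies overestimate external work: the pelvis point by
~46%, the bounding-box pseudo-CoM by ~143% — large but systematic, which
is why they can still track workload.

Cohort-level analysis (per-player correlations, pooled r with 95% CI,
Bland–Altman agreement) runs through `simulate_cohort()` +
`analyze_cohort()`, or end-to-end with outputs on disk through
`run_pipeline()`.

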