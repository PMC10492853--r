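# scgaze

Analysis of single-unit activity in the midbrain **superior colliculus (SC)**
during rapid **eye–head gaze shifts**, plus a forward simulator of the linear
ensemble-coding model of the SC motor map. The package is aimed at
sensorimotor neurophysiologists who record SC bursts together with 1-kHz gaze
and head traces and want a tested, reproducible implementation of the
movement-field, spike-density and trial-by-trial correlation analyses used in
this literature.

## The model in brief

Gaze-shift vectors (amplitude ΔG in deg, direction Φ) map onto anatomical SC
coordinates (u, v in mm) through the complex-logarithmic **afferent map**

    u = B_u · ln( √(ΔG² + 2·A·ΔG·cosΦ + A²) / A )
    v = B_v · atan2( ΔG·sinΦ, ΔG·cosΦ + A )

with B_u = 1.4 mm, B_v = 1.8 mm/rad, A = 3.0 deg. A neuron's burst spike
count follows the **static gain-field movement field**

    N_STMF(ΔG, Φ, E0) = N0 · (1 + ε·E0) · exp( −((u−u0)² + (v−v0)²) / 2σ_P² )

where E0 is the initial eye-in-head position and ε its (small) multiplicative
gain. Trial-to-trial count variability is **multiplicative (signal-dependent)
noise**: N_SPKS = (1 + n_MUL)·N_STMF + n_ADD with n_MUL ~ N(0, C_V).

Dynamically, the cumulative spike count (led by ΔT = 20 ms) is predicted to
grow linearly with the instantaneous straight-line gaze displacement Δg(t) —
slope α = N_STMF/ΔG — so the spike-density profile covaries with the
straight-line gaze velocity on single trials. The package implements the
phase-trajectory fits, the spike-density/velocity correlations, the
session-wide shuffle null with a one-tailed KS comparison, and a beta-shaped
fit P(r) = P0·(r+0.5)^α·(1−r)^β to correlation histograms.

The simulator generates full sessions from this model: population bursts on
the map, mini-spike-vector decoding of the desired trajectory, a fixed
population count threshold, a delayed linear plant
(v̇ = B·(c(t) − v(t−ΔT))), and eye-position-dependent kinematics (slower,
longer gaze shifts and larger head contributions for ipsilateral E0).

## Worked example

```r
library(scgaze)

cfg     <- sim_config(n_trials = 300, seed = 1)   # cell: N0 = 25, eps = 0.003,
session <- generate_session(cfg)                  # center (36.0, 23.3) deg
report  <- run_full_analysis(session, analysis_config(seed = 1))
print(report)
```

```
Analysis report (scgaze 0.1.0)
  300 events, 246 phase fits, 300 correlation records
  static field: Movement field: N0 = 24.7 spikes, eps = +0.002885 /deg, center (3.56, 0.681) mm, sigmaP = 0.597 mm
    fit r = 0.924
  count noise: slope C_V = 0.136, offset = 0.16 spikes (r = 0.94)
  original vs shuffled correlations: KS D = 0.797, p = 0
```

The fitted field recovers the generating cell: N0 = 24.7 vs 25 spikes,
ε = 0.0029 vs 0.003 per deg, and the map center (3.56, 0.681) mm is the
afferent image of a (35.5, 23.5) deg gaze vector vs the planted
(36.0, 23.3) deg. The mean–SD slope 0.136 estimates the generating
C_V = 0.15. Phase trajectories are nearly perfectly straight (median
deviation 0.06 spikes), and the spike-density/gaze-velocity correlations
(median r = 0.998 for bursts with ≥ 15 spikes) collapse to a median of 0.67
under the session shuffle — the KS test rejects equality decisively, showing
that the correlations reflect trial-specific kinematics, not stereotyped
profile shapes.

Sessions round-trip losslessly through a plain-text JSON format
(`write_session()` / `read_session()`), and `inst/scripts/sc-gaze.R` exposes
`simulate` and `analyze` verbs for shell use.

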