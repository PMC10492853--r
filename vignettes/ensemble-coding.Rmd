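---
title: "Ensemble coding of eye-head gaze shifts: models, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble coding of eye-head gaze shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scgaze)
```

## The scientific problem

A saccadic eye-head gaze shift is the rapid redirection of the eye in space,
ΔG(t) = ΔE(t) + ΔH(t). The intermediate and deep layers of the superior
colliculus (SC) hold a topographic motor map of such gaze shifts: *where* a
recruited population sits on the map encodes the amplitude and direction of
the movement, and — under the dynamic ensemble-coding view implemented here —
*when* its spikes are fired encodes the movement's instantaneous kinematics.
Each spike of each recruited cell contributes a fixed "mini vector"
determined by the cell's map site; the desired trajectory is the running
vector sum of all spikes, low-pass filtered by a downstream burst
generator/plant loop with a pure delay. Two testable consequences follow for
a *single* neuron:

1. its cumulative burst spike count, led by ΔT ≈ 20 ms, grows linearly with
   the instantaneous gaze displacement projected on the straight line from
   start to end point (slope α = N~STMF~/ΔG), and
2. its spike-density profile covaries with the straight-line gaze-velocity
   profile on a trial-by-trial basis.

Because eye-head gaze shifts have strongly variable kinematics — the same
35-deg displacement can be fast (eye-dominated) or slow (head-assisted),
depending on the initial eye-in-head position E0 — these predictions are
non-trivial: the correlations must survive genuine kinematic variability,
which is exactly what the session-shuffle null is designed to test.

## Models

**SC map.** The afferent map is complex-logarithmic with B~u~ = 1.4 mm,
B~v~ = 1.8 mm/rad and foveal shift A = 3 deg; `afferent_map()` and its
analytic inverse `efferent_map()` round-trip to better than 1e-9 over the
tested domain (amplitudes up to 100 deg, directions within ±80 deg, matching
the hemifield over which the calibration holds). Directions are taken in
degrees at the API and converted internally; the two-argument arctangent
keeps the quadrant, with a warning outside ±90 deg.

**Static gain-field movement field.** The burst count is a Gaussian in map
coordinates times an eye-position gain, N0·(1+ε·E0)·exp(−d²/2σ~P~²). ε is a
fractional modulation per degree (the "spikes/deg" label used in the field
refers to the same quantity via N0·ε). The five parameters are fitted by
Nelder–Mead least squares (`stats::optim`), unweighted on the raw integer
counts. Initialization is data-driven: map centroid weighted by counts, N0
from the 95th-percentile count, σ~P~ = 0.5 mm, ε = 0; a second simplex start
from the first optimum tightens convergence. The fit is isotropic in (u, v),
as the model specifies.

**Count noise.** N~SPKS~ = (1+n~MUL~)·N~STMF~ + n~ADD~, rounded and clipped
at zero. `noise_regression()` bins trials by *predicted* count (sliding bins
of 2 spikes, stepped by 1) and regresses the per-bin SD of the prediction
mismatch on the per-bin mean measured count. Using the mismatch — rather
than the raw SD of measured counts — matters numerically: the raw SD folds
in the within-bin spread of predictions (≈ 0.6 spikes for 2-spike bins),
which inflates the low-mean bins and biases the recovered C~V~ down by
0.01–0.02. Bins with fewer than 5 trials are dropped to avoid unstable SD
estimates.

**Dynamics.** Phase trajectories pair Δg(t) (Eq. above) with the smoothed
cumulative spike count shifted forward by the fixed 20-ms lead; straightness
is summarized by the SD of residuals around the per-trial OLS line (bursts
with < 10 spikes are excluded as too noisy, < 15 for the correlation
histograms; both configurable). The shuffle null permutes the assignment of
velocity profiles to spike-density profiles across the whole session,
allowing self-pairings, and computes each re-paired correlation over the
shorter of the two durations (truncation); linear resampling to a common
duration is available behind a flag. Correlation histograms use the
bin-width rule BW = range/√N and are summarized by the least-squares fit of
P0·(r+0.5)^α^·(1−r)^β^ on (−0.5, 1), whose mode is (α − 0.5β)/(α + β);
a maximum-likelihood alternative would weight sparse tails differently, but
the histogram least-squares form is the one this analysis tradition uses, so
it is the default. The scale P0 is profiled out analytically at each simplex
step, leaving a 2-parameter search in (log α, log β).

## The synthetic-data generator

The simulator is first-class, tested code: it forward-generates sessions
from the very model the analysis fits, which is what makes end-to-end
parameter recovery a meaningful check.

* **Default cell and paradigm.** N0 = 25 spikes, ε = 0.003/deg, field center
  at (36.0, 23.3) deg, σ~P~ = 0.6 mm, C~V~ = 0.15, E0 ∈ {−15, 0, +15} deg
  with the head at −E0 so gaze starts straight ahead; 600 trials per
  session. Targets are sampled log-normally around the field center
  (SD 0.35 in log-amplitude, 15 deg in direction) so that the session spans
  the amplitude/direction range a recording session aimed at a cell's field
  would contain.
* **Kinematics.** A beta-shaped (skewed) velocity profile integrates exactly
  to the amplitude. Duration = (20 ms + 1.5 ms/deg · ΔG + 2.5 ms/deg beyond
  35 deg) · (1 + 0.02·E0): peak velocity therefore rises with amplitude up
  to ~35 deg and falls beyond it (the growing head contribution), and
  ipsilateral eye positions slow the movement by ~45% relative to
  contralateral — the orderings the paradigm is built to produce. The head
  contribution is phenomenological: ΔH = max(0, 0.9·(ΔG + E0 − 35 deg))
  along the gaze direction, with a smooth ramp whose onset is delayed by
  40 − 2·E0 ms (earlier for ipsilateral eye positions).
* **Spike sampling.** By default the recorded cell's burst count is drawn
  from the multiplicative-noise count model and spike times are placed at
  quantiles of the normalized displacement profile ("count-matched"):
  the count statistics then carry exactly the modelled noise, and bursts are
  synchronized with the movement as the model assumes. An inhomogeneous
  Poisson mode (`spike_mode = "poisson"`) adds independent timing noise;
  it is the mode used for the population-decoding operations, where
  `sample_population_spikes()` thins each cell's rate profile at 1-ms
  resolution. Poisson timing noise adds ~√N count variance on top of the
  multiplicative term, which is why it is not the default for the recorded
  cell: it would bias the recovered mean–SD slope upward relative to the
  generating C~V~.
* **Decoder and plant.** The decoding calibration η is set so the expected
  population spike-vector sum equals the target vector for the centered
  target at E0 = 0. The plant is integrated by explicit 1-ms Euler stepping
  of v̇ = B(c − v(t−ΔT)); with the defaults B = 70/s, ΔT = 20 ms the loop is
  stable but lightly damped (B·ΔT = 1.4 < π/2), so the simulation keeps a
  3-s settle tail; the final displacement then equals the command area to
  well within 0.5%, and halving the Euler step moves endpoints by < 0.1%.

**What the generator does *not* emulate** — and hence what passing tests do
not show about real data: no VOR gain modulation, no oculomotor-range or
head-plant dynamics (only the phenomenological ΔH rule), no prelude or
post-saccadic activity, no multi-peaked or curved trajectories, no
recording artifacts (sorting errors, lost trials), and spike timing either
noiseless-synchronized or Poisson rather than the intermediate regularity of
real bursts. Recovery tests demonstrate that the *estimators are correct
under the model*, not that the model is true of the colliculus.

## Numerical choices

* **Differentiation/filtering.** Two-point central differences followed by a
  low-pass FIR (Hamming design, order 50, 80-Hz bandwidth at 1 kHz). The
  symmetric taps are normalized to unit DC gain and applied once as a
  *centered* convolution with reflection padding — exactly zero-phase for a
  linear-phase FIR, exact on constants and ramps, and free of the edge
  transients a forward–backward recursion produces. Zero phase matters
  because a filter delay would contaminate the 20-ms neural lead.
* **Detection.** Vectorial gaze speed must exceed 30 deg/s within an
  interval bounded by 20 deg/s crossings lasting ≥ 15 ms (standard saccade
  practice; the criteria are configurable). Detection is invariant to
  position offsets; peak times take the earliest sample on ties.
* **Spike densities.** Gaussian kernels are *not* truncated or renormalized
  at the selection-window edges; densities are evaluated on a grid extended
  by 5 kernel widths, and the cumulative curve uses exact Gaussian CDF sums,
  so total mass equals the spike count to machine precision. The adaptive
  kernel width equals the following inter-spike interval (preceding interval
  for the last spike — the choice is unspecified in the tradition and this
  is the symmetric-information option), clipped at 1 ms; bursts with fewer
  than two spikes fall back to the fixed 4-ms kernel with a warning.
* **Degenerate inputs.** Zero-amplitude events, collinear regression
  predictors (|r| > 0.999), all-identical gaze vectors, empty samples and
  zero-variance signals raise descriptive errors or flagged records rather
  than propagating NaNs; the pipeline reports per-stage failures without
  aborting independent stages.
* **Session storage.** Sessions persist as versioned JSON with float64
  vectors base64-encoded: plain text, loss-free round trip (general-purpose
  decimal JSON is not bit-exact for doubles).

## Problem sizes

The test suite runs the recovery analyses at the sizes the estimators need
rather than at full survey scale: 600-trial sessions for movement-field
recovery (20 replicate seeds), 750 trials for the C~V~ regression, 500
trials for the shuffle-null separation, 250 noiseless-envelope trials for
phase straightness, 100 trials for decoder conservation, and 3000 draws for
the beta-fit refit. These choices keep the default suite around a minute of
compute while leaving the statistical conclusions unambiguous.

## Known limitations

* The SC map calibration (and the tested inverse) covers the contralateral
  hemifield; directions beyond ±90 deg only warn.
* σ~P~ is isotropic in (u, v); elongated movement fields are not modelled.
* ΔT is fixed at 20 ms for all cells and trials; no per-cell optimization.
* The head contribution is a projected displacement rule, not a dynamical
  model; eye- versus head-position gain fields cannot be dissociated in the
  symmetric paradigm and are not separately parameterized.
* `ks_one_tailed()` uses the asymptotic two-sample statistic; with heavily
  tied correlation values the p-value is approximate (ties are suppressed).
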