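# Fixture builders shared across test files. Everything is generated in code.

# A trial whose gaze moves `amp` deg along `dir` (deg) with a skewed
# single-peaked velocity profile supported exactly on
# [onset, onset + dur] ms; optional head displacement dH along dir.
profile_trial <- function(amp = 30, dir = 0, E0 = 0, onset = 200, dur = 130,
                          total = 800, spikes = numeric(0), dH = 0,
                          trial_id = 1) {
  tt <- 0:total
  x <- (tt - onset) / dur
  v <- ifelse(x > 0 & x < 1, stats::dbeta(x, 2, 3), 0)
  dg <- cumsum(v)
  dg <- dg / dg[length(dg)] * amp
  ph <- dir * pi / 180
  hs <- dH * pmin(pmax(x, 0), 1)
  sc_trial(tt,
           gaze_h = dg * cos(ph), gaze_v = dg * sin(ph),
           head_h = -E0 * cos(ph) + hs * cos(ph),
           head_v = -E0 * sin(ph) + hs * sin(ph),
           spikes = spikes, E0 = E0, H0 = -E0, trial_id = trial_id)
}

# Events-with-counts table for movement-field fitting: a grid of gaze
# vectors crossed with the three initial eye positions.
mf_design <- function(n_amp = 10, n_dir = 10, amps = c(10, 80),
                      dirs = c(-20, 60)) {
  g <- expand.grid(dG = seq(amps[1], amps[2], length.out = n_amp),
                   phi = seq(dirs[1], dirs[2], length.out = n_dir),
                   E0 = c(-15, 0, 15))
  g
}

default_mf <- function() mf_params_center(25, 0.003, 36, 23.3, 0.6)
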