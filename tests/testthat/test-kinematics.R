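test_that("differentiation is exact on constants and ramps, ~exact in-band", {
  expect_equal(differentiate_trace(rep(5, 300)), rep(0, 300))
  ramp <- seq(0, 10, by = 0.1)   # 100 deg/s at 1 kHz
  v <- differentiate_trace(ramp)
  expect_equal(v[10:(length(v) - 10)], rep(100, length(v) - 19),
               tolerance = 1e-6)
  # 5 Hz, 10 deg sinusoid: analytic peak velocity 2*pi*5*10
  t <- (0:2000) / 1000
  v <- differentiate_trace(10 * sin(2 * pi * 5 * t))
  expect_equal(max(v[200:1800]), 2 * pi * 50, tolerance = 0.02)
  expect_error(differentiate_trace(rep(0, 30)), "filter order")
})

test_that("gaze-shift detection finds planted events and ignores stillness", {
  still <- profile_trial(amp = 1e-9)
  expect_equal(nrow(detect_gaze_shift(still)), 0)

  tr <- profile_trial(amp = 30, onset = 200, dur = 130)
  ev <- detect_gaze_shift(tr)
  expect_equal(nrow(ev), 1)
  # ground truth: where the continuous speed profile crosses the thresholds
  tau <- seq(0, 1, by = 1e-4)
  speed <- dbeta(tau, 2, 3) * 30 / 130 * 1000
  t_on_true <- 200 + 130 * tau[min(which(speed > 30))]
  t_off_true <- 200 + 130 * tau[max(which(speed > 20))]
  expect_lt(abs(ev$onset_ms - t_on_true), 3)
  expect_lt(abs(ev$offset_ms - t_off_true), 3)

  # detection is invariant to a constant position offset
  tr2 <- tr
  tr2$gaze_h <- tr2$gaze_h + 12
  expect_equal(detect_gaze_shift(tr2), ev)

  # two well-separated movements give two events in time order
  tt <- 0:1200
  x1 <- (tt - 200) / 100; x2 <- (tt - 700) / 100
  dg <- cumsum(ifelse(x1 > 0 & x1 < 1, dbeta(x1, 2, 3), 0) +
                 ifelse(x2 > 0 & x2 < 1, dbeta(x2, 2, 3), 0))
  dg <- dg / dg[length(dg)] * 60
  tr3 <- sc_trial(tt, dg, dg * 0, dg * 0, dg * 0)
  ev3 <- detect_gaze_shift(tr3)
  expect_equal(nrow(ev3), 2)
  expect_true(ev3$onset_ms[1] < ev3$onset_ms[2])
})

test_that("straight-line projection reduces to components and hits dG", {
  tr <- profile_trial(amp = 30, dir = 0)
  ev <- detect_gaze_shift(tr)[1, ]
  sld <- straight_line_displacement(tr, ev)
  expect_equal(sld$dg, tr$gaze_h - tr$gaze_h[sld$i_on], tolerance = 1e-12)
  expect_equal(sld$dg[sld$i_off], sld$dG)

  tr45 <- profile_trial(amp = 30, dir = 45)
  ev45 <- detect_gaze_shift(tr45)[1, ]
  s45 <- straight_line_displacement(tr45, ev45)
  x <- tr45$gaze_h - tr45$gaze_h[s45$i_on]
  expect_equal(s45$dg, sqrt(2) * x, tolerance = 1e-9)

  flat <- profile_trial(amp = 1e-9)
  expect_error(straight_line_displacement(
    flat, data.frame(onset_ms = 100, offset_ms = 100)), "after onset")
})

test_that("event metrics recover vector, peak velocity and head contribution", {
  # 3-4-5 gaze shift: 30 deg horizontal, 40 deg vertical
  tr <- profile_trial(amp = 50, dir = atan2(40, 30) * 180 / pi)
  ev <- event_metrics(tr, detect_gaze_shift(tr)[1, ])
  expect_equal(ev$dG, 50, tolerance = 5e-3)   # sub-threshold tails excluded
  expect_equal(ev$phi, 53.13, tolerance = 1e-3)
  expect_equal(ev$dH, 0)

  # planted peak velocity: amp/dur scaled so peak = 600 deg/s
  # beta(2,3) peak density = 16/9 at x = 1/3 -> vpk = (16/9)*amp/dur*1000
  amp <- 600 * 0.15 / (16 / 9)
  trv <- profile_trial(amp = amp, dir = 0, dur = 150)
  evv <- event_metrics(trv, detect_gaze_shift(trv)[1, ])
  expect_equal(evv$peak_velocity, 600, tolerance = 0.02)

  # head contribution projected on the gaze direction; the fixture head
  # ramps linearly over the profile support [200, 330]
  trh <- profile_trial(amp = 40, dir = 0, dH = 12)
  evh <- event_metrics(trh, detect_gaze_shift(trh)[1, ])
  ramp <- function(t) pmin(pmax((t - 200) / 130, 0), 1)
  expect_equal(evh$dH, 12 * (ramp(evh$offset_ms) - ramp(evh$onset_ms)),
               tolerance = 1e-6)
})

test_that("eye-in-head is gaze minus head on generated trials", {
  ses <- generate_session(sim_config(n_trials = 3, seed = 99))
  for (tr in ses$trials) {
    e <- eye_in_head(tr)
    expect_equal(e$h, tr$gaze_h - tr$head_h)
    expect_equal(e$h[1], tr$E0 * cos(tr$target[2] * pi / 180),
                 tolerance = 1e-9)
  }
})
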