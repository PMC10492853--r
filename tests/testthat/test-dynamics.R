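make_sld <- function(t, dg, gdot, i_on, i_off)
  list(t = t, dg = dg, gdot_lin = gdot, i_on = i_on, i_off = i_off)

make_density <- function(t, sd, n_spk)
  structure(list(t = t, sd = sd, csd = cumsum(sd), n_spk = n_spk,
                 method = "fixed", window = range(t)),
            class = "density_profile")

test_that("predicted cumulative count is linear in displacement", {
  mf <- default_mf()
  ctr <- efferent_map(mf$u0, mf$v0)
  ev <- data.frame(dG = ctr$dG, phi = ctr$phi, E0 = 0)
  n_stmf <- predict_static_count(ev$dG, ev$phi, 0, mf)
  dg <- seq(0, ev$dG, length.out = 100)
  ncs <- predict_cumulative_count(ev, mf, dg = dg)
  expect_equal(ncs[100], n_stmf)
  expect_equal(ncs[50], n_stmf * dg[50] / ev$dG)
  # alpha = N_STMF / dG: a 20-spike count over 50 deg gives 0.4 spikes/deg
  mf2 <- mf_params_center(20, 0, 50, 0, 0.6)
  ev2 <- data.frame(dG = 50, phi = 0, E0 = 0)
  expect_equal(predict_cumulative_count(ev2, mf2, dg = 1), 0.4)
  expect_error(predict_cumulative_count(data.frame(dG = 0, phi = 0, E0 = 0),
                                        mf, dg = 0), "zero-amplitude")
})

test_that("phase fit recovers an exact line with zero deviation", {
  dg <- seq(0, 50, by = 0.5)
  traj <- structure(list(t = seq_along(dg), dg = dg, ncs = 0.4 * dg,
                         n_spk = 20, dG = 50), class = "phase_trajectory")
  pf <- phase_fit_and_deviation(traj)
  expect_equal(pf$a, 0.4, tolerance = 1e-12)
  expect_equal(pf$b, 0, tolerance = 1e-12)
  expect_equal(pf$dev_sd, 0, tolerance = 1e-10)
  traj$n_spk <- 5
  expect_error(phase_fit_and_deviation(traj), "excluded")
})

test_that("SD-velocity correlation is 1 for proportional profiles, < 1 when skewed", {
  t <- 0:300
  x <- pmin(pmax((t - 50) / 150, 0), 1)
  vel <- dbeta(x, 2, 5)                 # skewed profile
  sld <- make_sld(t, cumsum(vel), vel, 51, 200)
  dens <- make_density(t, vel * 1e-3, 20)
  ev <- data.frame(peak_velocity = max(vel), peak_velocity_time = 80,
                   dH = 0, E0 = 0, duration_ms = 150)
  rec <- sd_velocity_correlation(dens, sld, ev, lead = 0, trial_id = 1)
  expect_equal(rec$r, 1, tolerance = 1e-12)
  expect_false(rec$flagged)
  # time-reversed density against skewed velocity: correlation drops
  dens_rev <- make_density(t, rev(vel) * 1e-3, 20)
  rec2 <- sd_velocity_correlation(dens_rev, sld, ev, lead = 0)
  expect_lt(rec2$r, 0.8)
  # zero-variance signal is flagged
  rec3 <- sd_velocity_correlation(make_density(t, rep(0, 301), 0), sld, ev,
                                  lead = 0)
  expect_true(rec3$flagged)
  expect_true(is.na(rec3$r))
})

test_that("shuffle null preserves profiles and degenerates for identical trials", {
  vel <- dbeta(seq(0, 1, length.out = 120), 2, 3)
  sdp <- vel * 1e-3
  sds <- replicate(12, sdp, simplify = FALSE)
  vels <- replicate(12, vel, simplify = FALSE)
  set.seed(5)
  r <- shuffle_null(sds, vels)
  expect_length(r, 12)
  expect_equal(r, rep(1, 12), tolerance = 1e-12)  # identical profiles
  # resampling flag returns the same length
  set.seed(5)
  r2 <- shuffle_null(sds, vels, resample = TRUE)
  expect_length(r2, 12)
  expect_error(shuffle_null(sds[1], vels[1]), "at least 2")
})

test_that("histogram bin width follows rho / sqrt(N)", {
  expect_equal(histogram_binwidth(1.5, 100), 0.15)
  expect_equal(histogram_binwidth(2, 1), 2)
  expect_equal(histogram_binwidth(0, 10), 0)
})

test_that("beta-shaped histogram fit: mode formula, argmax, and recovery", {
  # symmetric exponents put the mode at the support midpoint
  expect_equal((2 - 0.5 * 2) / (2 + 2), 0.25)
  set.seed(61)
  r_sym <- rcorr_beta(4000, 2, 2)
  bf_sym <- fit_beta_distribution(r_sym)
  expect_equal(bf_sym$mode_r, 0.25, tolerance = 0.1)

  # printed-parameter case: analytic mode of (r+.5)^1.71 (1-r)^0.70
  mode_ref <- (1.71 - 0.5 * 0.70) / (1.71 + 0.70)
  expect_equal(mode_ref, 0.5643, tolerance = 1e-3)

  set.seed(62)
  r <- rcorr_beta(3000, 1.71, 0.70)
  bf <- fit_beta_distribution(r)
  expect_equal(bf$alpha, 1.71, tolerance = 0.1)
  expect_equal(bf$beta, 0.70, tolerance = 0.1)
  # analytic mode equals the numerical argmax of the fitted curve
  grid <- seq(-0.499, 0.999, by = 1e-4)
  curve <- (grid + 0.5)^bf$alpha * (1 - grid)^bf$beta
  expect_equal(bf$mode_r, grid[which.max(curve)], tolerance = 2e-4)

  expect_warning(fit_beta_distribution(c(r, 1.2)), "excluded")
  expect_error(fit_beta_distribution(r[1:10]), "at least 50")
})

test_that("one-tailed KS rejects only shifts in the tested direction", {
  set.seed(71)
  a <- rnorm(500)
  expect_false(ks_one_tailed(a, a)$reject)
  b <- rnorm(500)
  expect_true(ks_one_tailed(b + 0.3, b)$reject)
  expect_false(ks_one_tailed(b - 0.5, b)$reject)  # shifted BELOW
  expect_error(ks_one_tailed(numeric(0), b), "empty")
})

test_that("z-scored partial regression dissociates the predictors", {
  set.seed(72)
  f <- rnorm(200); nuis <- rnorm(200)
  fit <- zscore_partial_regression(f, f, nuis, n_boot = 200)
  expect_equal(fit$p_sd$estimate, 1, tolerance = 1e-6)
  expect_equal(fit$p_ns$estimate, 0, tolerance = 0.05)
  # planted coefficients on orthogonalized predictors; the response is
  # restandardized internally, so the planted combination must have unit
  # variance to be recovered as-is
  fz <- scale(f)[, 1]
  nz <- scale(residuals(lm(nuis ~ f)))[, 1]
  v <- 0.8 * fz - 0.6 * nz
  fit2 <- zscore_partial_regression(v, fz, nz, n_boot = 400)
  expect_true(fit2$p_sd$ci[1] <= 0.8 && 0.8 <= fit2$p_sd$ci[2])
  expect_true(fit2$p_ns$ci[1] <= -0.6 && -0.6 <= fit2$p_ns$ci[2])
  expect_error(zscore_partial_regression(v, f, f + 1e-9 * nuis,
                                         n_boot = 10), "collinear")
})

test_that("endpoint clustering finds planted clusters and nothing else", {
  # all endpoints identical: a single cluster holding everything
  ev <- data.frame(dG_h = rep(30.4, 8), dG_v = rep(15.2, 8))
  cl <- cluster_gaze_shifts(ev, center = c(30, 15))
  expect_equal(nrow(cl$clusters), 1)
  expect_equal(cl$clusters$n, 8)
  # pairwise spread > 2 deg: nothing clusters
  ev2 <- data.frame(dG_h = 30 + 3 * (0:4), dG_v = rep(15, 5))
  cl2 <- cluster_gaze_shifts(ev2, center = c(33, 15))
  expect_equal(nrow(cl2$clusters), 0)
  # seven planted clusters of 4-5 trials at distinct grid cells
  set.seed(73)
  centers <- expand.grid(x = c(-5, -1, 3), y = c(-5, -1, 3))[1:7, ]
  rows <- do.call(rbind, lapply(seq_len(7), function(i) {
    n <- sample(4:5, 1)
    data.frame(dG_h = 30 + centers$x[i] + runif(n, 0.2, 1.8),
               dG_v = 15 + centers$y[i] + runif(n, 0.2, 1.8))
  }))
  cl3 <- cluster_gaze_shifts(rows, center = c(31, 16))
  expect_equal(nrow(cl3$clusters), 7)
  expect_equal(sum(cl3$clusters$n), nrow(rows))
})

test_that("peak regressions recover planted slopes and timing lead", {
  set.seed(74)
  n <- 60
  vpk <- runif(n, 300, 900)
  rec <- data.frame(trial_id = 1:n, r = 0.9, n_spk = rpois(n, 25),
                    peak_sd = 0.5 * vpk + rnorm(n, 0, 10),
                    peak_sd_time = 100 + (1:n) - 20,
                    peak_velocity = vpk,
                    peak_velocity_time = 100 + (1:n),
                    dH = 0, E0 = 0, duration_ms = 120, flagged = FALSE)
  pr <- peak_regressions(rec, n_boot = 200)
  expect_equal(pr$sd_slope$estimate, 0.5, tolerance = 0.05)
  expect_lt(abs(pr$nspk_slope$estimate), 0.02)
  expect_equal(pr$timing_lead_ms, -20)
  expect_error(peak_regressions(rec[1:5, ]), "at least 10")
})

test_that("head-amplitude effect regression recovers planted degradation", {
  set.seed(75)
  n <- 80
  dH <- runif(n, 0, 30)
  none <- data.frame(r = 0.85 + rnorm(n, 0, 0.03), dH = dH, n_spk = 20)
  h0 <- head_amplitude_effect(none)
  expect_lt(abs(h0$slope), 0.004)
  degraded <- data.frame(r = 0.9 - 0.009 * dH + rnorm(n, 0, 0.02), dH = dH,
                         n_spk = 20)
  h1 <- head_amplitude_effect(degraded)
  expect_lt(h1$slope, -0.005)
  expect_lt(h1$corr, -0.5)
  expect_error(head_amplitude_effect(none[1:4, ]), "at least 10")
})
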