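test_that("velocity profiles integrate to the amplitude and order with E0", {
  kin <- sim_config()$kin
  for (dG in c(5, 20, 50, 80)) for (E0 in c(-15, 0, 15)) {
    p <- make_velocity_profile(dG, E0, kin)
    expect_equal(sum(p$gdot) / 1000, dG, tolerance = 1e-6)
  }
  p_ipsi <- make_velocity_profile(50, 15, kin)
  p_contra <- make_velocity_profile(50, -15, kin)
  expect_gt(max(p_contra$gdot), max(p_ipsi$gdot))       # contra faster
  expect_gt(p_ipsi$duration, p_contra$duration)         # ipsi prolonged
  # peak velocity rises with amplitude then falls in the head regime
  vpk <- sapply(c(10, 20, 30, 50, 70), function(a)
    max(make_velocity_profile(a, 0, kin)$gdot))
  expect_true(all(diff(vpk[1:3]) > 0))
  expect_lt(vpk[5], vpk[3])
})

test_that("population rates are synchronized and mass-conserving", {
  set.seed(91)
  cfg <- sim_config()
  pop <- make_population_rates(36, 23.3, 10, cfg)
  dt <- diff(pop$t)[1]
  masses <- rowSums(pop$rates) * dt
  gain <- 1 + cfg$mf$eps * 10
  expect_equal(masses, pop$sites$n_exp * gain * (1 + pop$n_mul),
               tolerance = 1e-9)
  # every cell shares the same normalized envelope
  k <- which.max(pop$sites$n_exp)
  j <- which.min(abs(pop$sites$n_exp - median(pop$sites$n_exp)))
  expect_equal(cor(pop$rates[k, ], pop$rates[j, ]), 1, tolerance = 1e-12)
  expect_error(make_population_rates(-5, 0, 0, cfg), "outside")
})

test_that("Poisson sampling matches the rate mass", {
  set.seed(92)
  cfg <- sim_config()
  pop <- make_population_rates(36, 23.3, 0, cfg)
  k <- which.max(pop$sites$n_exp)
  mass <- sum(pop$rates[k, ]) * diff(pop$t)[1]
  counts <- replicate(800, {
    length(sample_population_spikes(pop)[[k]])
  })
  expect_lt(abs(mean(counts) - mass), 3 * sqrt(mass / 800))
  # zero rate gives no spikes
  pop0 <- pop; pop0$rates[] <- 0
  expect_true(all(lengths(sample_population_spikes(pop0)) == 0))
})

test_that("decoding turns single spikes into their site's mini vector", {
  cfg <- sim_config()
  uv <- afferent_map(50, 0, cfg$map)
  pop <- structure(list(sites = data.frame(u = uv$u, v = uv$v, n_exp = 1),
                        eta = 1, t = 0:10),
                   class = "sc_population")
  dec <- decode_desired_trajectory(list(5), pop, cfg)
  expect_equal(unname(dec$endpoint), c(50, 0), tolerance = 1e-9)
  pop$eta <- NA
  expect_error(decode_desired_trajectory(list(5), pop, cfg),
               "not calibrated")
})

test_that("count threshold truncates the population burst", {
  trains <- list(c(1, 5, 9), c(2, 6), c(3, 7, 11))
  expect_identical(apply_count_threshold(trains, Inf), trains)
  t1 <- apply_count_threshold(trains, 1)
  expect_equal(sum(lengths(t1)), 1)
  expect_equal(unlist(t1), 1)
  t4 <- apply_count_threshold(trains, 4)
  expect_equal(sum(lengths(t4)), 4)
  expect_equal(max(unlist(t4)), sort(unlist(trains))[4])
  expect_error(apply_count_threshold(trains, 0), "theta > 0")
})

test_that("plant has unit DC gain and a stable first-order limit", {
  z <- simulate_plant(rep(0, 100))
  expect_equal(max(abs(z$e)), 0)
  prof <- make_velocity_profile(30, 0)
  pl <- simulate_plant(prof$gdot, B = 70, delta_T = 20)
  expect_equal(pl$e[length(pl$e)], 30, tolerance = 0.005)
  # no delay: v' = B(c - v); step command has the closed-form lag response
  B <- 70
  cmd <- rep(100, 400)
  p0 <- simulate_plant(cmd, B = B, delta_T = 0, t_settle = 0)
  tt <- p0$t / 1000
  v_ref <- 100 * (1 - exp(-B * tt))
  expect_lt(max(abs(p0$v - v_ref)), 1.5)   # Euler error, deg/s on a 100 deg/s step
  expect_error(simulate_plant(rep(1, 10), B = 100, delta_T = 20),
               "unstable")
})

test_that("sessions are reproducible and show the head-contribution pattern", {
  cfg <- sim_config(n_trials = 40, seed = 123)
  s1 <- generate_session(cfg)
  s2 <- generate_session(cfg)
  expect_identical(s1$trials[[7]]$gaze_h, s2$trials[[7]]$gaze_h)
  expect_identical(s1$trials[[7]]$spikes, s2$trials[[7]]$spikes)

  # head contribution grows with amplitude and with ipsilateral E0
  cfg2 <- sim_config(n_trials = 150, seed = 124)
  s <- generate_session(cfg2)
  info <- do.call(rbind, lapply(s$trials, function(tr) {
    n <- length(tr$t)
    dh <- sqrt((tr$head_h[n] - tr$head_h[1])^2 +
                 (tr$head_v[n] - tr$head_v[1])^2)
    data.frame(amp = tr$target[1], E0 = tr$E0, dH = dh)
  }))
  big <- info$amp > 45
  expect_gt(mean(info$dH[big]), mean(info$dH[!big]))
  mid <- info$amp > 25 & info$amp < 60
  expect_gt(mean(info$dH[mid & info$E0 == 15]),
            mean(info$dH[mid & info$E0 == -15]))
})

test_that("count statistics across a session carry the multiplicative noise", {
  cfg <- sim_config(n_trials = 750, seed = 321,
                    noise = noise_params(0.20, 0))
  ses <- generate_session(cfg)
  rows <- lapply(ses$trials, function(tr) {
    ev <- primary_gaze_shift(tr)
    if (is.null(ev)) return(NULL)
    data.frame(dG = ev$dG, phi = ev$phi, E0 = ev$E0,
               n_spk = select_burst_spikes(tr$spikes, ev)$n_spk)
  })
  d <- do.call(rbind, rows)
  pred <- predict_static_count(d$dG, d$phi, d$E0, cfg$mf, cfg$map)
  nr <- noise_regression(pred, d$n_spk)
  expect_equal(nr$slope, 0.20, tolerance = 0.2)
  expect_lt(abs(nr$slope - 0.20), 0.04)
})
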