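#' Configuration of the forward ensemble-coding simulator
#'
#' Bundles every parameter of the synthetic-session generator: the SC map,
#' the recorded cell's movement field and count-noise model, the recruited
#' population, the downstream burst generator/plant, the gaze-kinematics
#' model, and the eye-position paradigm. Defaults reproduce the study
#' conditions: a cell with N0 = 25 spikes, eye-position sensitivity
#' 0.003/deg, movement-field center at (36.0 deg, 23.3 deg), sigmaP = 0.6 mm;
#' multiplicative count noise C_V = 0.15; burst gain B = 70/s and neural lead
#' 20 ms; initial eye-in-head positions E0 in \{-15, 0, +15\} deg with the
#' head at -E0 so gaze starts straight ahead.
#'
#' @param map A [map_params()] object.
#' @param mf The recorded cell's [mf_params()].
#' @param noise A [noise_params()] object (trial-to-trial count noise).
#' @param n_pop Approximate number of recruited cells, default 200.
#' @param pop_sigma Extent of the recruited population on the map (mm),
#'   default 0.5.
#' @param B Burst-generator gain (1/s), default 70.
#' @param delta_T Neural lead of SC output (ms), default 20.
#' @param theta_fixed Optional population spike-count threshold (spikes).
#' @param kin Gaze-kinematics parameters: `d0` (ms), `d1` (ms/deg), `d2`
#'   (extra ms/deg beyond `amp_knee`), `amp_knee` (deg, head-contribution
#'   regime), `e0_gain` (fractional duration change per deg of E0), `shape_p`,
#'   `shape_q` (beta-shaped velocity profile exponents).
#' @param head Head-contribution parameters: `k1` (gain), `omr_margin` (deg,
#'   oculomotor-range soft limit), `delay0` (ms), `delay_e0` (ms/deg; head
#'   onset is `delay0 - delay_e0 * E0` after gaze onset), `dur_factor` (head
#'   movement duration in gaze durations).
#' @param E0_levels Initial eye-in-head positions (deg), symmetric.
#' @param n_trials Number of trials, default 600.
#' @param target_spread `amp_sd_log` (SD of log-amplitude around the field
#'   center) and `dir_sd` (deg) of the sampled targets.
#' @param spike_mode `"count_matched"` (default): the burst count is drawn
#'   from the multiplicative-noise count model and spike times are placed at
#'   displacement quantiles (synchronized bursts); or `"poisson"`:
#'   inhomogeneous Poisson sampling of the rate envelope.
#' @param seed Optional integer seed; sessions are reproducible given
#'   (config, seed).
#'
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(map = map_params(),
                       mf = mf_params_center(25, 0.003, 36, 23.3, 0.6, map),
                       noise = noise_params(0.15, 0),
                       n_pop = 200, pop_sigma = 0.5,
                       B = 70, delta_T = 20, theta_fixed = NULL,
                       kin = list(d0 = 20, d1 = 1.5, d2 = 2.5,
                                  amp_knee = 35, e0_gain = 0.02,
                                  shape_p = 2, shape_q = 3),
                       head = list(k1 = 0.9, omr_margin = 35, delay0 = 40,
                                   delay_e0 = 2, dur_factor = 2.5),
                       E0_levels = c(-15, 0, 15),
                       n_trials = 600,
                       target_spread = list(amp_sd_log = 0.35, dir_sd = 15),
                       spike_mode = c("count_matched", "poisson"),
                       seed = NULL) {
  spike_mode <- match.arg(spike_mode)
  stopifnot(B > 0, delta_T >= 0)
  if (B * delta_T / 1000 >= pi / 2)
    stop("unstable plant loop: need B * delta_T < pi/2")
  if (!isTRUE(all.equal(sort(E0_levels), sort(-E0_levels))))
    stop("E0 levels must be symmetric about zero")
  structure(list(map = map, mf = mf, noise = noise, n_pop = n_pop,
                 pop_sigma = pop_sigma, B = B, delta_T = delta_T,
                 theta_fixed = theta_fixed, kin = kin, head = head,
                 E0_levels = E0_levels, n_trials = n_trials,
                 target_spread = target_spread, spike_mode = spike_mode,
                 seed = seed),
            class = "sim_config")
}

#' Gaze velocity profile of the kinematics generator
#'
#' A beta-shaped (skewed, single-peaked) velocity profile along the
#' straight-line gaze direction whose time integral equals the gaze-shift
#' amplitude exactly. Duration grows with amplitude (with an extra
#' head-contribution term beyond `amp_knee`) and with ipsilateral initial eye
#' position, so peak velocity rises with amplitude up to ~`amp_knee` deg and
#' falls beyond it, and is reduced for ipsilateral E0.
#'
#' @param dG Gaze-shift amplitude (deg), > 0.
#' @param E0 Initial eye-in-head position (deg).
#' @param kin Kinematics parameter list (see [sim_config()]).
#' @param dt Time step (ms), default 1.
#'
#' @return A list: `t` (ms from movement onset), `gdot` (deg/s),
#'   `duration` (ms).
#' @export
make_velocity_profile <- function(dG, E0,
                                  kin = sim_config()$kin, dt = 1) {
  stopifnot(dG > 0)
  D <- (kin$d0 + kin$d1 * dG + kin$d2 * max(0, dG - kin$amp_knee)) *
    (1 + kin$e0_gain * E0)
  D <- max(round(D / dt) * dt, 20)
  tt <- seq(0, D, by = dt)
  shape <- stats::dbeta(tt / D, kin$shape_p, kin$shape_q)
  gdot <- shape * dG / D * 1000
  gdot <- gdot * dG / (sum(gdot) * dt / 1000)    # exact displacement
  list(t = tt, gdot = gdot, duration = D)
}

#' Expected rate profiles of the recruited SC population
#'
#' Places a lattice of cells on the SC map around the afferent image of the
#' target vector. Cell k's expected burst count is a Gaussian of its map
#' distance from that image (extent `pop_sigma`), gain-modulated by the
#' initial eye position; all cells share the normalized velocity-profile
#' envelope (synchronized bursts, led by `delta_T` ms), scaled per cell. A
#' single zero-mean Gaussian multiplicative factor per trial scales the whole
#' population (signal-dependent noise). The decoding calibration constant
#' `eta` is set so that the expected population spike-vector sum equals the
#' target vector at E0 = 0.
#'
#' @param dG,phi Target gaze vector (deg), amplitude > 0, |phi| <= 90.
#' @param E0 Initial eye-in-head position (deg).
#' @param config A [sim_config()] object.
#' @param profile Optional velocity profile from [make_velocity_profile()].
#'
#' @return An object of class `"sc_population"`: `sites` (data.frame `u`,
#'   `v`, `n_exp`), `rates` (cells x time matrix, spikes/ms), `t` (ms; burst
#'   window, leading the movement by `delta_T`), `eta`, `n_mul`, `target`.
#' @export
make_population_rates <- function(dG, phi, E0, config = sim_config(),
                                  profile = NULL) {
  if (dG <= 0 || abs(phi) > 90)
    stop("target outside the calibrated map region")
  if (is.null(profile))
    profile <- make_velocity_profile(dG, E0, config$kin)
  ctr <- afferent_map(dG, phi, config$map)
  m <- ceiling(sqrt(config$n_pop))
  g <- seq(-3, 3, length.out = m) * config$pop_sigma
  sites <- expand.grid(u = ctr$u + g, v = ctr$v + g)
  sites <- sites[sites$u >= 0, ]
  d2 <- (sites$u - ctr$u)^2 + (sites$v - ctr$v)^2
  n_exp <- config$mf$N0 * exp(-d2 / (2 * config$pop_sigma^2))
  gain <- 1 + config$mf$eps * E0
  n_mul <- stats::rnorm(1, 0, config$noise$c_v)
  env <- profile$gdot / (dG * 1000)               # unit-area envelope, 1/ms
  rates <- outer(n_exp * gain * (1 + n_mul), env)
  mv <- efferent_map(sites$u, sites$v, config$map)
  mx <- sum(n_exp * mv$dG * cos(mv$phi * pi / 180))
  my <- sum(n_exp * mv$dG * sin(mv$phi * pi / 180))
  eta <- sqrt(mx^2 + my^2) / dG
  structure(list(sites = data.frame(u = sites$u, v = sites$v, n_exp = n_exp),
                 rates = rates, t = profile$t - config$delta_T,
                 eta = eta, n_mul = n_mul, target = c(dG = dG, phi = phi)),
            class = "sc_population")
}

#' Sample population spike trains by Poisson thinning
#'
#' Draws an inhomogeneous Poisson spike train per cell at 1-ms resolution
#' from its rate profile; cells are independent given the shared envelope.
#'
#' @param pop An [make_population_rates()] object.
#' @return List of numeric vectors (sorted spike times, ms), one per cell.
#' @export
sample_population_spikes <- function(pop) {
  stopifnot(inherits(pop, "sc_population"))
  dt <- diff(pop$t)[1]
  lapply(seq_len(nrow(pop$rates)), function(k) {
    counts <- stats::rpois(ncol(pop$rates), pop$rates[k, ] * dt)
    if (!sum(counts)) return(numeric(0))
    sort(rep(pop$t, counts) + stats::runif(sum(counts), 0, dt))
  })
}

#' Decode the desired gaze trajectory from population spikes
#'
#' The dynamic ensemble-coding readout: each spike of cell k contributes a
#' mini gaze vector equal to the efferent image of its map site divided by
#' the calibration constant `eta`, delivered `delta_T` ms after the spike;
#' the desired trajectory is the running vector sum.
#'
#' @param spike_trains List of spike-time vectors, one per cell (see
#'   [sample_population_spikes()]).
#' @param pop The [make_population_rates()] object carrying sites and `eta`.
#' @param config A [sim_config()] object (for `delta_T`).
#' @param dt Output sampling (ms), default 1.
#'
#' @return A list: `t` (ms), `x`, `y` (deg; cumulative decoded displacement),
#'   and `endpoint` = `c(x, y)` at the last sample.
#' @export
decode_desired_trajectory <- function(spike_trains, pop,
                                      config = sim_config(), dt = 1) {
  stopifnot(inherits(pop, "sc_population"))
  if (is.null(pop$eta) || !is.finite(pop$eta) || pop$eta <= 0)
    stop("population is not calibrated (eta missing)")
  mv <- efferent_map(pop$sites$u, pop$sites$v, config$map)
  mx <- mv$dG * cos(mv$phi * pi / 180) / pop$eta
  my <- mv$dG * sin(mv$phi * pi / 180) / pop$eta
  all_t <- unlist(spike_trains) + config$delta_T
  all_x <- rep(mx, vapply(spike_trains, length, integer(1)))
  all_y <- rep(my, vapply(spike_trains, length, integer(1)))
  o <- order(all_t)
  all_t <- all_t[o]; all_x <- all_x[o]; all_y <- all_y[o]
  t0 <- if (length(all_t)) floor(min(all_t)) else 0
  t1 <- if (length(all_t)) ceiling(max(all_t)) else 0
  grid <- seq(t0, t1, by = dt)
  idx <- findInterval(grid, all_t)
  cx <- c(0, cumsum(all_x)); cy <- c(0, cumsum(all_y))
  x <- cx[idx + 1L]; y <- cy[idx + 1L]
  list(t = grid, x = x, y = y,
       endpoint = c(x = sum(all_x), y = sum(all_y)))
}

#' Truncate population activity at a fixed spike-count threshold
#'
#' Discards every spike fired after the cumulative population spike count
#' reaches `theta` — the downstream mechanism that stops the burst generator
#' once the total number of spikes exceeds a fixed threshold.
#'
#' @param spike_trains List of spike-time vectors, one per cell.
#' @param theta Threshold (spikes), > 0; `Inf` leaves the input unchanged.
#' @return The truncated list of spike trains.
#' @export
apply_count_threshold <- function(spike_trains, theta) {
  stopifnot(theta > 0)
  if (!is.finite(theta)) return(spike_trains)
  pooled <- sort(unlist(spike_trains))
  if (length(pooled) <= theta) return(spike_trains)
  t_cut <- pooled[ceiling(theta)]
  lapply(spike_trains, function(s) s[s <= t_cut])
}

#' Simulate the downstream burst-generator/plant loop
#'
#' Explicit 1-ms Euler integration of the delay-differential realization of
#' the downstream transfer (a local feedback loop with pure delay):
#' \deqn{\dot v(t) = B\,(c(t) - v(t - \Delta T)), \qquad e(t) = \int v}
#' For a command of finite area the final position converges to that area
#' (unit DC gain). The loop is stable for \eqn{B \Delta T < \pi/2}.
#'
#' @param command Desired-velocity command (deg/s) sampled at `dt` ms.
#' @param B Burst-generator gain (1/s), default 70.
#' @param delta_T Loop delay (ms), default 20.
#' @param dt Euler step (ms), default 1.
#' @param t_settle Extra simulated time after the command ends (ms),
#'   default 3000 (the loop is lightly damped near `B * delta_T = pi/2` and
#'   needs a long tail to ring out).
#'
#' @return A list: `t` (ms), `e` (deg, position), `v` (deg/s).
#' @export
simulate_plant <- function(command, B = 70, delta_T = 20, dt = 1,
                           t_settle = 3000) {
  if (B * delta_T / 1000 >= pi / 2)
    stop("unstable plant loop: need B * delta_T < pi/2")
  d <- round(delta_T / dt)
  c_full <- c(command, rep(0, round(t_settle / dt)))
  n <- length(c_full)
  v <- numeric(n)
  h <- dt / 1000
  for (i in seq_len(n - 1L)) {
    v_del <- if (i > d) v[i - d] else 0
    v[i + 1L] <- v[i] + h * B * (c_full[i] - v_del)
  }
  if (max(abs(v)) > 50 * max(abs(command), 1e-12))
    stop("plant response is growing: instability detected")
  list(t = seq(0, by = dt, length.out = n), e = cumsum(v) * h, v = v)
}

smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x^3 * (10 - 15 * x + 6 * x^2)
}

# spike times at displacement quantiles of the velocity profile, led by
# delta_T: the cumulative count then tracks the straight-line displacement.
quantile_spike_times <- function(n, profile, lead) {
  if (n < 1) return(numeric(0))
  cum <- cumsum(profile$gdot) / sum(profile$gdot)
  q <- (seq_len(n) - 0.5) / n
  stats::approx(cum, profile$t, xout = q, ties = "ordered")$y - lead
}

#' Generate a complete synthetic recording session
#'
#' Forward-simulates `n_trials` eye-head gaze shifts to targets sampled in and
#' around the recorded cell's movement field, with the initial eye-in-head
#' position drawn from the paradigm levels (head at -E0, gaze starting
#' straight ahead). Gaze traces follow the straight-line kinematics generator;
#' head traces add a smooth contribution that grows with amplitude and
#' ipsilateral eye position and starts later for contralateral eye positions.
#' The recorded cell's spike train is sampled from its movement-field count
#' model (see `spike_mode` in [sim_config()]). Fully reproducible from
#' (config, seed).
#'
#' @param config A [sim_config()] object.
#' @return An object of class `"sc_session"`: list with `trials` (list of
#'   [sc_trial()]), `cell` (mf/map/site metadata) and `config`.
#' @export
generate_session <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  ctr <- efferent_map(config$mf$u0, config$mf$v0, config$map)
  trials <- vector("list", config$n_trials)
  for (i in seq_len(config$n_trials)) {
    E0 <- sample(config$E0_levels, 1)
    amp <- min(max(ctr$dG * exp(stats::rnorm(1, 0, config$target_spread$amp_sd_log)),
                   3), 90)
    dir <- min(max(ctr$phi + stats::rnorm(1, 0, config$target_spread$dir_sd),
                   -80), 80)
    prof <- make_velocity_profile(amp, E0, config$kin)
    D <- prof$duration
    t_on <- 300
    ph <- dir * pi / 180
    # head contribution along the gaze direction
    dH <- max(0, config$head$k1 * (amp + E0 - config$head$omr_margin))
    h_delay <- max(0, config$head$delay0 - config$head$delay_e0 * E0)
    h_dur <- config$head$dur_factor * D
    n_ms <- t_on + max(D + 300, round(h_delay + h_dur) + 100)
    tt <- 0:n_ms
    dg <- numeric(n_ms + 1L)
    idx <- (t_on + 1L):(t_on + length(prof$t))
    dg[idx] <- cumsum(prof$gdot) / 1000
    if (max(idx) < n_ms + 1L) dg[(max(idx) + 1L):(n_ms + 1L)] <- dg[max(idx)]
    dg <- dg * amp / dg[n_ms + 1L]
    gaze_h <- dg * cos(ph); gaze_v <- dg * sin(ph)
    hs <- dH * smoothstep((tt - t_on - h_delay) / h_dur)
    head_h <- -E0 * cos(ph) + hs * cos(ph)
    head_v <- -E0 * sin(ph) + hs * sin(ph)
    n_stmf <- predict_static_count(amp, dir, E0, config$mf, config$map)
    if (config$spike_mode == "count_matched") {
      n_spk <- sample_spike_count(n_stmf, config$noise)
      spk <- quantile_spike_times(n_spk, prof, config$delta_T) + t_on
    } else {
      n_mul <- stats::rnorm(1, 0, config$noise$c_v)
      lam <- n_stmf * max(0, 1 + n_mul) * prof$gdot / (amp * 1000)
      counts <- stats::rpois(length(lam), lam)
      spk <- sort(rep(prof$t, counts) + stats::runif(sum(counts))) -
        config$delta_T + t_on
    }
    spk <- spk[spk >= 0 & spk <= n_ms]
    trials[[i]] <- sc_trial(tt, gaze_h, gaze_v, head_h, head_v, sort(spk),
                            E0 = E0, H0 = -E0, target = c(amp, dir),
                            trial_id = i)
  }
  structure(list(trials = trials,
                 cell = list(mf = config$mf, map = config$map,
                             site = c(u = config$mf$u0, v = config$mf$v0),
                             center_deg = c(Rc = ctr$dG, Phic = ctr$phi)),
                 config = config),
            class = "sc_session")
}

#' @export
print.sc_session <- function(x, ...) {
  cat(sprintf("SC session: %d trials, cell at (%.2f, %.2f) mm [%s spikes]\n",
              length(x$trials), x$cell$site["u"], x$cell$site["v"],
              x$config$spike_mode))
  invisible(x)
}
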