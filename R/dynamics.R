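#' Predicted cumulative spike count along the gaze trajectory
#'
#' The dynamic movement-field model predicts that the cumulative spike count
#' of a recruited neuron, led by `lead` ms, grows linearly with the
#' instantaneous straight-line gaze displacement:
#' \deqn{n_{CS}(t - \Delta T) = \frac{N_{STMF}}{\Delta G}\, \Delta g(t)}
#' so the phase-line slope is \eqn{\alpha = N_{STMF} / \Delta G} spikes/deg.
#'
#' @param event A completed gaze-shift event (see [event_metrics()]), with
#'   `dG`, `phi`, `E0`.
#' @param mf An [mf_params()] object.
#' @param map A [map_params()] object.
#' @param dg Straight-line displacement samples (deg), e.g. from
#'   [straight_line_displacement()].
#'
#' @return Predicted cumulative count at each `dg` sample (spikes).
#' @export
predict_cumulative_count <- function(event, mf, map = map_params(), dg) {
  if (event$dG <= 0) stop("zero-amplitude gaze shift")
  n_stmf <- predict_static_count(event$dG, event$phi, event$E0, mf, map)
  (n_stmf / event$dG) * dg
}

#' Phase trajectory of a gaze shift
#'
#' Pairs the instantaneous straight-line gaze displacement \eqn{\Delta g(t)}
#' with the smoothed cumulative spike count \eqn{n_{CS}(t - \Delta T)}
#' (density profile shifted forward by the neural lead), sampled at 1 kHz over
#' the gaze-shift interval.
#'
#' @param trial An [sc_trial()] object.
#' @param event A one-row event data.frame.
#' @param density A `"density_profile"` of the selected burst.
#' @param lead Neural lead (ms), default 20.
#'
#' @return An object of class `"phase_trajectory"`: list with `t` (ms), `dg`
#'   (deg), `ncs` (spikes), `n_spk`, `dG`, `event`.
#' @export
phase_trajectory <- function(trial, event, density, lead = 20) {
  sld <- straight_line_displacement(trial, event)
  idx <- sld$i_on:sld$i_off
  tt <- sld$t[idx]
  structure(list(t = tt, dg = sld$dg[idx],
                 ncs = density_at(density, tt - lead, "csd"),
                 n_spk = density$n_spk, dG = sld$dG, event = event),
            class = "phase_trajectory")
}

#' Straight-line fit and deviation of a phase trajectory
#'
#' Ordinary least-squares line \eqn{\hat n_{CS} = a\,\Delta g + b} through the
#' phase-trajectory samples, and the standard deviation of the instantaneous
#' deviations \eqn{\hat d(t) = n_{CS} - \hat n_{CS}} (spikes). Trajectories
#' from bursts with fewer than `min_spikes` spikes are too noisy for a
#' meaningful line and are rejected.
#'
#' @param traj A [phase_trajectory()] object.
#' @param min_spikes Minimum burst count, default 10.
#'
#' @return A list: `a` (slope, spikes/deg), `b` (offset, spikes), `dev_sd`
#'   (spikes), `n_spk`, `dG`.
#' @export
phase_fit_and_deviation <- function(traj, min_spikes = 10) {
  stopifnot(inherits(traj, "phase_trajectory"))
  if (traj$n_spk < min_spikes)
    stop(sprintf("burst has %d spikes (< %d): excluded from phase fits",
                 traj$n_spk, min_spikes))
  fit <- stats::lm(ncs ~ dg, data = list(ncs = traj$ncs, dg = traj$dg))
  dev <- stats::residuals(fit)
  list(a = unname(stats::coef(fit)[2]), b = unname(stats::coef(fit)[1]),
       dev_sd = stats::sd(dev), n_spk = traj$n_spk, dG = traj$dG)
}

#' Correlate delayed spike density with straight-line gaze velocity
#'
#' Pearson correlation between the spike density shifted forward by the
#' neural lead, \eqn{SD(t - \Delta T)}, and the straight-line gaze velocity
#' \eqn{\dot G_{lin}(t)}, sampled at 1 kHz over the gaze-shift interval.
#' Returns a one-row record carrying the correlation together with the
#' per-trial quantities used in downstream population analyses.
#'
#' @param density A `"density_profile"` of the selected burst.
#' @param sld Output of [straight_line_displacement()] for the same event.
#' @param event The completed event row (for peak velocity, dH, E0).
#' @param lead Neural lead (ms), default 20.
#' @param trial_id Identifier copied into the record.
#'
#' @return A one-row data.frame: `trial_id`, `r`, `n_spk`, `peak_sd`
#'   (spikes/s), `peak_sd_time` (ms), `peak_velocity` (deg/s),
#'   `peak_velocity_time` (ms), `dH`, `E0`, `duration_ms`, `flagged`
#'   (TRUE when a zero-variance signal makes r undefined).
#' @export
sd_velocity_correlation <- function(density, sld, event, lead = 20,
                                    trial_id = NA) {
  idx <- sld$i_on:sld$i_off
  tt <- sld$t[idx]
  sd_shift <- density_at(density, tt - lead, "sd")
  vel <- sld$gdot_lin[idx]
  flagged <- stats::sd(sd_shift) == 0 || stats::sd(vel) == 0
  r <- if (flagged) NA_real_ else stats::cor(sd_shift, vel)
  ipk <- which.max(sd_shift)
  data.frame(trial_id = trial_id, r = r, n_spk = density$n_spk,
             peak_sd = 1000 * max(sd_shift), peak_sd_time = tt[ipk],
             peak_velocity = event$peak_velocity,
             peak_velocity_time = event$peak_velocity_time,
             dH = event$dH, E0 = event$E0,
             duration_ms = event$duration_ms, flagged = flagged)
}

#' Shuffle null for spike-density/gaze-velocity correlations
#'
#' Randomly permutes the assignment of gaze-velocity profiles to spike-density
#' profiles across the whole session and recomputes the trial-by-trial
#' correlations. Self-pairings are allowed. Because re-paired profiles differ
#' in duration, each correlation is computed over the shorter of the pair's
#' durations (truncation); alternatively both profiles can be linearly
#' resampled to the velocity profile's duration (`resample = TRUE`).
#'
#' @param sd_profiles List of per-trial spike-density vectors (already shifted
#'   by the neural lead onto the gaze-shift interval, 1-ms sampling).
#' @param vel_profiles List of per-trial straight-line velocity vectors on the
#'   same intervals.
#' @param resample Logical; see above. Default FALSE (truncation).
#'
#' @return Numeric vector of null correlations (one per trial; NA when a
#'   truncated pair has zero variance).
#' @export
shuffle_null <- function(sd_profiles, vel_profiles, resample = FALSE) {
  n <- length(sd_profiles)
  if (n < 2L || length(vel_profiles) != n)
    stop("need matched lists of at least 2 spike-density and velocity profiles")
  perm <- sample.int(n)
  vapply(seq_len(n), function(i) {
    s <- sd_profiles[[i]]
    v <- vel_profiles[[perm[i]]]
    if (resample) {
      m <- length(v)
      s <- stats::approx(seq_along(s), s, xout = seq(1, length(s),
                                                     length.out = m))$y
    } else {
      m <- min(length(s), length(v))
      s <- s[seq_len(m)]; v <- v[seq_len(m)]
    }
    if (stats::sd(s) == 0 || stats::sd(v) == 0) return(NA_real_)
    stats::cor(s, v)
  }, numeric(1))
}

#' Histogram bin width rule
#'
#' \eqn{BW = \rho / \sqrt{N}} with \eqn{\rho} the range of the variable and
#' `N` the number of data points. A zero range is degenerate (single bin) and
#' returns 0.
#'
#' @param rho Range of the variable, >= 0.
#' @param N Number of data points, >= 1.
#' @return Bin width (same units as `rho`).
#' @export
histogram_binwidth <- function(rho, N) {
  stopifnot(rho >= 0, N >= 1)
  if (rho == 0) return(0)
  rho / sqrt(N)
}

#' Fit a beta-shaped curve to a correlation histogram
#'
#' Correlation histograms over the support \eqn{(-0.5, 1)} are summarized by
#' \deqn{P(r) = P_0 (r + 0.5)^\alpha (1 - r)^\beta}
#' fitted by least squares to the histogram densities (bin width
#' \eqn{1.5/\sqrt{N}} by default). The mode follows analytically as
#' \eqn{r^* = (\alpha - 0.5\beta) / (\alpha + \beta)}.
#'
#' @param r Correlation coefficients; values outside (-0.5, 1) are excluded
#'   with a warning.
#' @param bin_width Histogram bin width; default [histogram_binwidth()] with
#'   rho = 1.5.
#'
#' @return An object of class `"beta_fit"`: list with `P0`, `alpha`, `beta`,
#'   `mode_r`, `bins` (data.frame `mid`, `density`), `n`.
#' @export
fit_beta_distribution <- function(r, bin_width = NULL) {
  r <- r[!is.na(r)]
  out <- r <= -0.5 | r >= 1
  if (any(out)) {
    warning(sprintf("%d correlation(s) outside (-0.5, 1) excluded", sum(out)))
    r <- r[!out]
  }
  if (length(r) < 50L) stop("need at least 50 correlations for a beta fit")
  if (is.null(bin_width)) bin_width <- histogram_binwidth(1.5, length(r))
  breaks <- seq(-0.5, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  h <- graphics::hist(r, breaks = breaks, plot = FALSE)
  mid <- h$mids; dens <- h$density
  # moment-based start: (r + 0.5)/1.5 ~ Beta(alpha + 1, beta + 1)
  x <- (r + 0.5) / 1.5
  m <- mean(x); v <- stats::var(x)
  k <- max(m * (1 - m) / v - 1, 0.1)
  a0 <- max(m * k - 1, 0.05); b0 <- max((1 - m) * k - 1, 0.05)
  shape <- function(al, be) (mid + 0.5)^al * (1 - mid)^be
  obj <- function(p) {
    al <- exp(p[1]); be <- exp(p[2])
    s <- shape(al, be)
    p0 <- sum(s * dens) / sum(s^2)      # profile out the scale analytically
    sum((dens - p0 * s)^2)
  }
  opt <- stats::optim(c(log(a0), log(b0)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  alpha <- exp(opt$par[1]); beta <- exp(opt$par[2])
  s <- shape(alpha, beta)
  P0 <- sum(s * dens) / sum(s^2)
  structure(list(P0 = P0, alpha = alpha, beta = beta,
                 mode_r = (alpha - 0.5 * beta) / (alpha + beta),
                 bins = data.frame(mid = mid, density = dens),
                 n = length(r)),
            class = "beta_fit")
}

#' @export
print.beta_fit <- function(x, ...) {
  cat(sprintf(
    "Beta-shaped fit on (-0.5, 1): alpha = %.3g, beta = %.3g, mode r = %.3f (n = %d)\n",
    x$alpha, x$beta, x$mode_r, x$n))
  invisible(x)
}

#' Draw correlations from the beta-shaped distribution
#'
#' Samples from the density proportional to \eqn{(r+0.5)^\alpha (1-r)^\beta}
#' on \eqn{(-0.5, 1)} via the affine map of a standard Beta
#' (\eqn{r = 1.5 x - 0.5} with \eqn{x \sim Beta(\alpha+1, \beta+1)}).
#'
#' @param n Number of draws.
#' @param alpha,beta Shape exponents, > 0.
#' @return Numeric vector in (-0.5, 1).
#' @export
rcorr_beta <- function(n, alpha, beta) {
  stopifnot(alpha > 0, beta > 0)
  1.5 * stats::rbeta(n, alpha + 1, beta + 1) - 0.5
}

#' Cluster gaze-shift endpoints near the movement-field center
#'
#' Bins gaze-shift endpoints on a square grid (default 2 x 2 deg) within
#' `radius` deg of the field center; bins holding at least `min_size` events
#' form clusters of near-identical gaze shifts, within which kinematics can
#' vary while the motor goal is fixed.
#'
#' @param events Data.frame with endpoint columns `dG_h`, `dG_v` (deg).
#' @param center Field center in gaze coordinates `c(x, y)` deg (e.g.
#'   `Rc * c(cos, sin)(Phic)`).
#' @param bin Bin side (deg), default 2.
#' @param min_size Minimum events per cluster, default 3 (configurable 3-5).
#' @param radius Maximum endpoint distance from the center (deg), default 10.
#'
#' @return A list: `events` (input with an added `cluster` column, NA when
#'   unclustered) and `clusters` (data.frame with `cluster`, `n`, bin-center
#'   coordinates `x`, `y`). `clusters` may have zero rows.
#' @export
cluster_gaze_shifts <- function(events, center, bin = 2, min_size = 3,
                                radius = 10) {
  stopifnot(all(c("dG_h", "dG_v") %in% names(events)), length(center) == 2L)
  dx <- events$dG_h - center[1]; dy <- events$dG_v - center[2]
  near <- sqrt(dx^2 + dy^2) <= radius
  ix <- floor((events$dG_h - (center[1] - radius)) / bin)
  iy <- floor((events$dG_v - (center[2] - radius)) / bin)
  key <- ifelse(near, paste(ix, iy, sep = ","), NA)
  tab <- table(key[!is.na(key)])
  good <- names(tab)[tab >= min_size]
  cluster <- match(key, good)
  events$cluster <- cluster
  clusters <- if (length(good)) {
    parts <- do.call(rbind, strsplit(good, ","))
    data.frame(cluster = seq_along(good), n = as.integer(tab[good]),
               x = (as.numeric(parts[, 1]) + 0.5) * bin + center[1] - radius,
               y = (as.numeric(parts[, 2]) + 0.5) * bin + center[2] - radius)
  } else {
    data.frame(cluster = integer(0), n = integer(0), x = numeric(0),
               y = numeric(0))
  }
  list(events = events, clusters = clusters)
}

boot_slope_ci <- function(x, y, n_boot, level, fun) {
  est <- fun(x, y)
  n <- length(x)
  bs <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, replace = TRUE)
    fun(x[idx], y[idx])
  }, numeric(1))
  ci <- stats::quantile(bs, c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE, names = FALSE)
  list(estimate = est, ci = ci)
}

#' Peak spike density and spike count versus peak gaze velocity
#'
#' Univariate regressions of the per-trial peak spike density (spikes/s) and
#' burst spike count on the peak gaze velocity, with bootstrap confidence
#' intervals, plus the mean timing difference between the peak of the spike
#' density (lead-shifted) and the peak of the gaze velocity (negative = the
#' neural peak leads).
#'
#' @param records Data.frame of correlation records
#'   ([sd_velocity_correlation()] rows).
#' @param n_boot Bootstrap resamples, default 1000.
#' @param level Confidence level, default 0.95.
#'
#' @return A list: `sd_slope` and `nspk_slope` (each `estimate` + `ci`),
#'   `timing_lead_ms` (mean of `peak_sd_time - peak_velocity_time`), `n`.
#' @export
peak_regressions <- function(records, n_boot = 1000, level = 0.95) {
  rec <- records[!is.na(records$peak_sd) & !is.na(records$peak_velocity), ]
  if (nrow(rec) < 10L) stop("need at least 10 records for peak regressions")
  slope <- function(x, y) unname(stats::coef(stats::lm(y ~ x))[2])
  list(
    sd_slope = boot_slope_ci(rec$peak_velocity, rec$peak_sd, n_boot, level,
                             slope),
    nspk_slope = boot_slope_ci(rec$peak_velocity, rec$n_spk, n_boot, level,
                               slope),
    timing_lead_ms = mean(rec$peak_sd_time - rec$peak_velocity_time),
    n = nrow(rec))
}

#' Partial regression of peak gaze velocity on z-scored predictors
#'
#' Standardizes peak gaze velocity, peak spike density and burst spike count
#' to zero mean and unit SD and fits, without intercept,
#' \deqn{\hat V_{PK} = p_{SD} \hat F_{PK} + p_{NS} \hat N_{SPK}}
#' to dissociate which predictor carries the velocity information. Bootstrap
#' confidence intervals at `1 - alpha`.
#'
#' @param v_pk Peak gaze velocities (deg/s).
#' @param f_pk Peak spike densities (spikes/s).
#' @param n_spk Burst spike counts.
#' @param n_boot Bootstrap resamples, default 1000.
#' @param alpha Significance level for the CIs, default 0.01.
#'
#' @return A list: `p_sd`, `p_ns` (each `estimate` + `ci`), `n`.
#' @export
zscore_partial_regression <- function(v_pk, f_pk, n_spk, n_boot = 1000,
                                      alpha = 0.01) {
  n <- length(v_pk)
  stopifnot(length(f_pk) == n, length(n_spk) == n)
  if (n < 20L) stop("need at least 20 records for the partial regression")
  if (stats::sd(v_pk) == 0 || stats::sd(f_pk) == 0 || stats::sd(n_spk) == 0)
    stop("zero variance in a regression variable")
  if (abs(stats::cor(f_pk, n_spk)) > 0.999)
    stop("predictors are collinear")
  z <- function(x) (x - mean(x)) / stats::sd(x)
  coefs <- function(idx) {
    d <- data.frame(v = z(v_pk[idx]), f = z(f_pk[idx]), s = z(n_spk[idx]))
    unname(stats::coef(stats::lm(v ~ 0 + f + s, data = d)))
  }
  est <- coefs(seq_len(n))
  bs <- t(vapply(seq_len(n_boot),
                 function(i) coefs(sample.int(n, replace = TRUE)),
                 numeric(2)))
  qs <- c(alpha / 2, 1 - alpha / 2)
  list(p_sd = list(estimate = est[1],
                   ci = stats::quantile(bs[, 1], qs, names = FALSE)),
       p_ns = list(estimate = est[2],
                   ci = stats::quantile(bs[, 2], qs, names = FALSE)),
       n = n)
}

#' Effect of head-movement amplitude on rate-velocity coupling
#'
#' Linear regression of the per-trial spike-density/gaze-velocity correlation
#' on the head contribution to the gaze shift, restricted to well-sampled
#' bursts. A negative slope means the rate-velocity coupling degrades as the
#' head contributes more.
#'
#' @param records Data.frame of correlation records with columns `r`, `dH`,
#'   `n_spk`.
#' @param min_nspk Burst-count inclusion criterion, default 15.
#'
#' @return A list: `r0` (offset), `slope` (per deg), `corr` (Pearson r),
#'   `r_squared`, `n`.
#' @export
head_amplitude_effect <- function(records, min_nspk = 15) {
  rec <- records[!is.na(records$r) & records$n_spk >= min_nspk, ]
  if (nrow(rec) < 10L)
    stop("need at least 10 qualifying records for the head-effect regression")
  fit <- stats::lm(r ~ dH, data = rec)
  cr <- stats::cor(rec$dH, rec$r)
  list(r0 = unname(stats::coef(fit)[1]), slope = unname(stats::coef(fit)[2]),
       corr = cr, r_squared = cr^2, n = nrow(rec))
}

#' One-tailed two-sample Kolmogorov-Smirnov test
#'
#' Tests whether sample `a` is shifted to higher values than sample `b`
#' (i.e. the empirical CDF of `a` lies below that of `b`).
#'
#' @param a,b Numeric samples (each size >= 20 for a meaningful test).
#' @param alpha Significance level, default 0.005.
#'
#' @return A list: `statistic`, `p_value`, `reject` (logical).
#' @export
ks_one_tailed <- function(a, b, alpha = 0.005) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("empty sample")
  if (length(a) < 20L || length(b) < 20L)
    warning("samples smaller than 20: KS test may be unreliable")
  kt <- suppressWarnings(stats::ks.test(a, b, alternative = "less"))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       reject = kt$p.value < alpha)
}
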