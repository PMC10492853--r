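#' Static gain-field movement-field parameters
#'
#' The number of spikes an SC neuron fires in its saccade-related burst is
#' modelled as a Gaussian sensitivity profile in SC map coordinates,
#' multiplicatively modulated by the initial eye-in-head position:
#' \deqn{N_{STMF}(\Delta G, \Phi, E_0) = N_0 (1 + \varepsilon E_0)
#'   \exp\!\left(-\frac{(u-u_0)^2 + (v-v_0)^2}{2\sigma_P^2}\right)}
#' with \eqn{(u, v)} from [afferent_map()].
#'
#' @param N0 Peak spike count (spikes), > 0.
#' @param eps Eye-position sensitivity (fractional modulation per deg; the
#'   field convention "spikes/deg" labels the same quantity).
#' @param u0,v0 Field center on the SC map (mm).
#' @param sigmaP Field extent on the map (mm), > 0.
#'
#' @return An object of class `"mf_params"`.
#' @seealso [mf_params_center()] to give the center as a gaze vector.
#' @export
mf_params <- function(N0, eps, u0, v0, sigmaP) {
  stopifnot(is.numeric(N0), is.numeric(eps), is.numeric(u0), is.numeric(v0),
            is.numeric(sigmaP))
  if (N0 <= 0) stop("N0 must be positive")
  if (sigmaP <= 0) stop("sigmaP must be positive")
  structure(list(N0 = N0, eps = eps, u0 = u0, v0 = v0, sigmaP = sigmaP),
            class = "mf_params")
}

#' Movement-field parameters from a gaze-vector center
#'
#' @param N0,eps,sigmaP See [mf_params()].
#' @param Rc,Phic Optimal gaze-shift amplitude (deg) and direction (deg).
#' @param map A [map_params()] object.
#' @return An `"mf_params"` object with `u0`, `v0` at the afferent image of
#'   `(Rc, Phic)`.
#' @export
mf_params_center <- function(N0, eps, Rc, Phic, sigmaP, map = map_params()) {
  ct <- afferent_map(Rc, Phic, map)
  mf_params(N0, eps, ct$u, ct$v, sigmaP)
}

#' @export
print.mf_params <- function(x, ...) {
  cat(sprintf(
    "Movement field: N0 = %.3g spikes, eps = %+.4g /deg, center (%.3g, %.3g) mm, sigmaP = %.3g mm\n",
    x$N0, x$eps, x$u0, x$v0, x$sigmaP))
  invisible(x)
}

#' Predicted burst spike count of the static gain-field model
#'
#' @param dG Gaze-shift amplitude(s), deg.
#' @param phi Gaze-shift direction(s), deg.
#' @param E0 Initial eye-in-head position(s), deg.
#' @param mf An [mf_params()] object.
#' @param map A [map_params()] object.
#'
#' @return Real-valued predicted count(s) `N_STMF` (spikes).
#' @export
#' @examples
#' mf <- mf_params_center(25, 0.003, 36, 23.3, 0.6)
#' predict_static_count(36, 23.3, 0, mf)     # = N0 at the center
predict_static_count <- function(dG, phi, E0, mf, map = map_params()) {
  stopifnot(inherits(mf, "mf_params"))
  gain <- 1 + mf$eps * E0
  if (any(gain <= 0))
    stop("eye-position gain (1 + eps*E0) must stay positive over the data")
  uv <- afferent_map(dG, phi, map)
  d2 <- (uv$u - mf$u0)^2 + (uv$v - mf$v0)^2
  mf$N0 * gain * exp(-d2 / (2 * mf$sigmaP^2))
}

#' Fit the static gain-field movement field
#'
#' Least-squares fit of the five parameters (N0, eps, u0, v0, sigmaP) to
#' measured burst spike counts by the Nelder-Mead simplex, started from a
#' data-driven initialization (count-weighted centroid of the afferent-mapped
#' gaze vectors; N0 from the 95th percentile count; sigmaP = 0.5 mm; eps = 0).
#' Counts enter unweighted, as raw integers. Goodness of fit is the Pearson
#' correlation between predicted and measured counts.
#'
#' @param data A data.frame with columns `dG`, `phi` (deg), `E0` (deg) and
#'   `n_spk` (measured burst counts).
#' @param map A [map_params()] object.
#' @param init Optional initial `"mf_params"` (otherwise data-driven).
#' @param control Passed to [stats::optim()]; sensible defaults are supplied.
#'
#' @return An object of class `"mf_fit"`: list with `params` (`"mf_params"`),
#'   `r` (Pearson), `fitted` (predicted counts), `sse`, `n_trials`,
#'   `converged`.
#' @export
fit_static_field <- function(data, map = map_params(), init = NULL,
                             control = list()) {
  need <- c("dG", "phi", "E0", "n_spk")
  if (!all(need %in% names(data)))
    stop("data must have columns dG, phi, E0, n_spk")
  if (nrow(data) < 10L)
    stop("need at least 10 events to fit a movement field")
  if (length(unique(round(data$dG, 6))) < 2L ||
      length(unique(round(data$phi, 6))) < 2L)
    stop("degenerate design: gaze vectors must span several amplitudes and directions")
  uv <- afferent_map(data$dG, data$phi, map)
  n <- data$n_spk
  if (is.null(init)) {
    w <- pmax(n, 0); w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(n), length(n))
    init <- mf_params(N0 = max(stats::quantile(n, 0.95), 1), eps = 0,
                      u0 = sum(w * uv$u), v0 = sum(w * uv$v), sigmaP = 0.5)
  }
  obj <- function(p) {
    N0 <- p[1]; eps <- p[2]; u0 <- p[3]; v0 <- p[4]; sP <- p[5]
    if (N0 <= 0 || sP <= 1e-4) return(1e12)
    gain <- 1 + eps * data$E0
    if (any(gain <= 0)) return(1e12)
    pred <- N0 * gain * exp(-((uv$u - u0)^2 + (uv$v - v0)^2) / (2 * sP^2))
    sum((n - pred)^2)
  }
  p0 <- c(init$N0, init$eps, init$u0, init$v0, init$sigmaP)
  ctrl <- utils::modifyList(
    list(maxit = 5000, reltol = 1e-12,
         parscale = c(max(p0[1], 1), 0.01, 1, 1, 0.5)), control)
  opt <- stats::optim(p0, obj, method = "Nelder-Mead", control = ctrl)
  # one restart from the optimum tightens the simplex
  opt <- stats::optim(opt$par, obj, method = "Nelder-Mead", control = ctrl)
  pars <- mf_params(opt$par[1], opt$par[2], opt$par[3], opt$par[4],
                    abs(opt$par[5]))
  fitted <- predict_static_count(data$dG, data$phi, data$E0, pars, map)
  r <- if (stats::sd(fitted) > 0) stats::cor(fitted, n) else NA_real_
  structure(list(params = pars, r = r, fitted = fitted, sse = opt$value,
                 n_trials = nrow(data), converged = opt$convergence == 0L),
            class = "mf_fit")
}

#' @export
print.mf_fit <- function(x, ...) {
  print(x$params)
  cat(sprintf("  r = %.3f over %d trials%s\n", x$r, x$n_trials,
              if (x$converged) "" else " (fit not converged)"))
  invisible(x)
}

#' Spike-count noise parameters
#'
#' Trial-to-trial variability of the burst count is modelled as multiplicative
#' (signal-dependent) noise with coefficient of variation `c_v` plus additive
#' noise of standard deviation `sigma_add`:
#' \deqn{N_{SPKS} = (1 + n_{MUL}) N_{STMF} + n_{ADD}}, with
#' \eqn{n_{MUL} \sim N(0, C_V)} and \eqn{n_{ADD} \sim N(0, \sigma_{ADD})}.
#'
#' @param c_v Coefficient of variation (dimensionless), >= 0.
#' @param sigma_add Additive noise SD (spikes), >= 0.
#' @return An object of class `"noise_params"`.
#' @export
noise_params <- function(c_v = 0.15, sigma_add = 0) {
  if (c_v < 0 || sigma_add < 0) stop("noise parameters must be non-negative")
  structure(list(c_v = c_v, sigma_add = sigma_add), class = "noise_params")
}

#' Sample noisy burst spike counts
#'
#' Draws integer spike counts from the multiplicative + additive noise model
#' around the predicted count, rounded to the nearest integer and clipped at
#' zero. Uses R's global RNG; seed upstream for reproducibility.
#'
#' @param n_stmf Predicted count(s), >= 0 (vectorized).
#' @param noise A [noise_params()] object.
#' @return Non-negative integer count(s), same length as `n_stmf`.
#' @export
sample_spike_count <- function(n_stmf, noise = noise_params()) {
  stopifnot(inherits(noise, "noise_params"))
  if (any(n_stmf < 0)) stop("predicted counts must be non-negative")
  k <- length(n_stmf)
  raw <- (1 + stats::rnorm(k, 0, noise$c_v)) * n_stmf +
    stats::rnorm(k, 0, noise$sigma_add)
  pmax(0, round(raw))
}

#' Mean-SD regression of spike-count variability
#'
#' Orders trials by the predicted count (descending), forms sliding bins of
#' width `bin_width` predicted spikes stepped by `step` spikes, and within
#' each bin computes the mean of the measured counts together with the
#' standard deviation of the prediction mismatch (measured minus predicted;
#' using the mismatch removes the within-bin spread of predictions from the
#' scatter). The line SD = a + b * mean is then fitted across bins. A slope
#' b well above zero with a near-zero offset is the signature of
#' multiplicative (signal-dependent) noise, with b estimating the
#' coefficient of variation. Bins with fewer than `min_per_bin` trials are
#' dropped.
#'
#' @param n_pred Predicted counts (e.g. `fitted` from [fit_static_field()]).
#' @param n_obs Measured counts, same length.
#' @param bin_width Bin width in predicted spikes, default 2.
#' @param step Bin step in predicted spikes, default 1.
#' @param min_per_bin Minimum trials per bin, default 5.
#' @param min_bins Minimum number of populated bins, default 10.
#'
#' @return A list: `offset` (a, spikes), `slope` (b = C_V estimate), `r`
#'   (Pearson correlation of the binned points), `bins` (data.frame with
#'   `mean`, `sd`, `n`).
#' @export
noise_regression <- function(n_pred, n_obs, bin_width = 2, step = 1,
                             min_per_bin = 5, min_bins = 10) {
  stopifnot(length(n_pred) == length(n_obs))
  lo <- floor(min(n_pred)); hi <- max(n_pred)
  starts <- seq(lo, hi, by = step)
  rows <- lapply(starts, function(b) {
    sel <- n_pred >= b & n_pred < b + bin_width
    if (sum(sel) < min_per_bin) return(NULL)
    data.frame(mean = mean(n_obs[sel]),
               sd = stats::sd(n_obs[sel] - n_pred[sel]), n = sum(sel))
  })
  bins <- do.call(rbind, rows)
  if (is.null(bins) || nrow(bins) < min_bins)
    stop(sprintf("too few populated bins (%d < %d) for the mean-SD regression",
                 if (is.null(bins)) 0L else nrow(bins), min_bins))
  fit <- stats::lm(sd ~ mean, data = bins)
  r <- if (stats::sd(bins$sd) > 0) stats::cor(bins$mean, bins$sd) else
    NA_real_  # scatter identically flat: correlation undefined
  list(offset = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       r = r, bins = bins)
}
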