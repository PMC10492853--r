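#' Select the saccade-related burst spikes of a gaze shift
#'
#' Keeps the spikes falling in the window that equals the gaze-shift duration
#' but leads it by `lead` ms: from `onset - lead` to `offset - lead`. Spikes
#' before the window belong to the prelude, spikes after it to post-saccadic
#' activity; both are discarded.
#'
#' @param spikes Spike times (ms), sorted ascending.
#' @param event A one-row data.frame with `onset_ms` and `offset_ms`.
#' @param lead Neural lead time (ms), default 20.
#'
#' @return An object of class `"spike_burst"`: list with `spike_times`,
#'   `n_spk` and `window` (the selection window, ms).
#' @export
#' @examples
#' ev <- data.frame(onset_ms = 0, offset_ms = 150)
#' select_burst_spikes(c(-30, -15, 0, 50, 120, 200), ev)
select_burst_spikes <- function(spikes, event, lead = 20) {
  if (event$offset_ms <= event$onset_ms)
    stop("event offset must lie after onset")
  if (is.unsorted(spikes)) stop("spike times must be sorted")
  win <- c(event$onset_ms - lead, event$offset_ms - lead)
  kept <- spikes[spikes >= win[1] & spikes <= win[2]]
  structure(list(spike_times = as.numeric(kept), n_spk = length(kept),
                 window = win),
            class = "spike_burst")
}

#' @export
print.spike_burst <- function(x, ...) {
  cat(sprintf("Burst: %d spikes in [%g, %g] ms\n", x$n_spk,
              x$window[1], x$window[2]))
  invisible(x)
}

density_grid <- function(burst, sigma_max, pad = 5) {
  lo <- floor(burst$window[1] - pad * sigma_max)
  hi <- ceiling(burst$window[2] + pad * sigma_max)
  seq(lo, hi, by = 1)
}

make_density <- function(burst, sigmas, grid, method) {
  tau <- burst$spike_times
  sd <- numeric(length(grid))
  csd <- numeric(length(grid))
  for (i in seq_along(tau)) {
    sd <- sd + stats::dnorm(grid, tau[i], sigmas[i])
    csd <- csd + stats::pnorm(grid, tau[i], sigmas[i])
  }
  structure(list(t = grid, sd = sd, csd = csd, method = method,
                 sigma_k = sigmas, n_spk = burst$n_spk,
                 window = burst$window),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("Spike density (%s kernel): %d spikes on [%g, %g] ms\n",
              x$method, x$n_spk, min(x$t), max(x$t)))
  invisible(x)
}

#' Spike density with a fixed Gaussian kernel
#'
#' Convolves each spike with a normalized Gaussian kernel of standard
#' deviation `sigma` (ms). The density `sd` is in spikes/ms (multiply by 1000
#' for spikes/s); `csd` is the cumulative kernel mass (exact Gaussian CDF
#' sums, so total mass equals the number of spikes). Kernels are not truncated
#' at the selection-window edges: the profile is evaluated on a grid extended
#' by `pad` kernel widths so that unit mass per spike is preserved.
#'
#' @param burst A [select_burst_spikes()] object.
#' @param sigma Kernel standard deviation (ms), default 4.
#' @param grid Optional evaluation grid (ms, 1-ms steps); default extends the
#'   burst window by `pad * sigma` on both sides.
#' @param pad Grid extension in kernel widths, default 5.
#'
#' @return A `"density_profile"`: list with `t`, `sd` (spikes/ms), `csd`
#'   (spikes), `method`, `sigma_k`, `n_spk`, `window`.
#' @export
spike_density_fixed <- function(burst, sigma = 4, grid = NULL, pad = 5) {
  stopifnot(inherits(burst, "spike_burst"), sigma > 0)
  if (is.null(grid)) grid <- density_grid(burst, sigma, pad)
  make_density(burst, rep(sigma, burst$n_spk), grid, "fixed")
}

adaptive_widths <- function(tau, min_width = 1) {
  isi <- diff(tau)
  pmax(c(isi, isi[length(isi)]), min_width)  # last spike: preceding interval
}

#' Spike density with an adaptive (inter-spike-interval) kernel
#'
#' Each spike is convolved with a Gaussian kernel whose width equals the local
#' inter-spike interval (the interval following the spike; the last spike uses
#' the preceding one), clipped below at 1 ms. Short intervals (high rates)
#' thus get sharper kernels, long intervals broader ones. Bursts with fewer
#' than two spikes fall back to the fixed 4-ms kernel with a warning.
#'
#' @inheritParams spike_density_fixed
#' @param min_width Minimum kernel width (ms), default 1.
#'
#' @return A `"density_profile"`; see [spike_density_fixed()].
#' @export
spike_density_adaptive <- function(burst, grid = NULL, min_width = 1,
                                   pad = 5) {
  stopifnot(inherits(burst, "spike_burst"))
  if (burst$n_spk < 2L) {
    warning("fewer than 2 spikes: falling back to fixed 4-ms kernel")
    return(spike_density_fixed(burst, sigma = 4, grid = grid, pad = pad))
  }
  sig <- adaptive_widths(burst$spike_times, min_width)
  if (is.null(grid)) grid <- density_grid(burst, max(sig), pad)
  make_density(burst, sig, grid, "adaptive")
}

#' Discrete firing rate from inter-spike intervals
#'
#' The instantaneous rate attributed to each inter-spike interval:
#' \eqn{\dot n(i) = 1000 / (\tau_{i+1} - \tau_i)} spikes/s on
#' \eqn{[\tau_i, \tau_{i+1})}.
#'
#' @param burst A [select_burst_spikes()] object with at least 2 spikes.
#' @return A data.frame with `t_start`, `t_end` (ms) and `rate` (spikes/s).
#' @export
isi_rate <- function(burst) {
  stopifnot(inherits(burst, "spike_burst"))
  if (burst$n_spk < 2L) stop("need at least 2 spikes for an ISI rate")
  tau <- burst$spike_times
  isi <- diff(tau)
  if (any(isi == 0)) stop("duplicate spike times give an infinite rate")
  data.frame(t_start = tau[-length(tau)], t_end = tau[-1], rate = 1000 / isi)
}

#' Evaluate a density profile at given times
#'
#' Linear interpolation of `sd` and `csd` on the profile grid; times outside
#' the grid return 0 (`sd`) or the boundary mass (`csd`).
#'
#' @param density A `"density_profile"`.
#' @param t_ms Times (ms).
#' @param what `"sd"` or `"csd"`.
#' @return Numeric vector.
#' @export
density_at <- function(density, t_ms, what = c("sd", "csd")) {
  what <- match.arg(what)
  y <- density[[what]]
  lo <- if (what == "sd") 0 else 0
  hi <- if (what == "sd") 0 else y[length(y)]
  stats::approx(density$t, y, xout = t_ms, yleft = lo, yright = hi)$y
}
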