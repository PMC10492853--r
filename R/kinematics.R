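#' Construct a behavioural trial
#'
#' A trial bundles the 1-kHz gaze and head position traces (horizontal and
#' vertical components, deg), the single-unit spike event times (ms), and the
#' initial conditions of the eye-head paradigm. The eye-in-head trace is not
#' stored; it is defined component-wise as gaze minus head (E = G - H), see
#' [eye_in_head()].
#'
#' @param t Time grid (ms), uniform 1-ms steps.
#' @param gaze_h,gaze_v Gaze position traces (deg), same length as `t`.
#' @param head_h,head_v Head position traces (deg), same length as `t`.
#' @param spikes Spike event times (ms), sorted ascending, within `range(t)`.
#' @param E0 Initial eye-in-head position (deg), signed along the gaze-shift
#'   direction (positive = ipsilateral to the upcoming shift).
#' @param H0 Initial head position (deg); defaults to `-E0` (initial gaze
#'   straight ahead).
#' @param target Target location `c(amplitude, direction)` in deg, or `NULL`.
#' @param trial_id Identifier (integer or character).
#'
#' @return An object of class `"sc_trial"`.
#' @export
sc_trial <- function(t, gaze_h, gaze_v, head_h, head_v, spikes = numeric(0),
                     E0 = 0, H0 = -E0, target = NULL, trial_id = NA) {
  n <- length(t)
  if (n < 2L) stop("trial needs at least two samples")
  if (!isTRUE(all.equal(diff(t), rep(diff(t)[1], n - 1L), tolerance = 1e-8)))
    stop("time grid must be uniform")
  for (nm in c("gaze_h", "gaze_v", "head_h", "head_v")) {
    tr <- get(nm)
    if (length(tr) != n) stop(sprintf("trace '%s' length differs from t", nm))
    if (anyNA(tr)) stop(sprintf("trace '%s' contains NA", nm))
  }
  spikes <- as.numeric(spikes)
  if (is.unsorted(spikes)) stop("spike times must be sorted ascending")
  if (length(spikes) && (spikes[1] < t[1] || spikes[length(spikes)] > t[n]))
    stop("spike times must lie within the trial time grid")
  structure(list(t = as.numeric(t), gaze_h = as.numeric(gaze_h),
                 gaze_v = as.numeric(gaze_v), head_h = as.numeric(head_h),
                 head_v = as.numeric(head_v), spikes = spikes,
                 E0 = E0, H0 = H0, target = target, trial_id = trial_id),
            class = "sc_trial")
}

#' @export
print.sc_trial <- function(x, ...) {
  cat(sprintf("Trial %s: %d ms, %d spikes, E0 = %+g deg\n",
              as.character(x$trial_id), length(x$t) - 1L, length(x$spikes),
              x$E0))
  invisible(x)
}

#' Eye-in-head traces of a trial
#'
#' @param trial An [sc_trial()] object.
#' @return A list with components `h` and `v` (deg): gaze minus head.
#' @export
eye_in_head <- function(trial) {
  list(h = trial$gaze_h - trial$head_h, v = trial$gaze_v - trial$head_v)
}

# Symmetric FIR low-pass taps (Hamming window design) normalized to unit DC
# gain. Applied once as a centered convolution, which is exactly zero-phase.
lowpass_taps <- function(order = 50, cutoff_hz = 80, fs = 1000) {
  b <- as.numeric(signal::fir1(order, cutoff_hz / (fs / 2)))
  b / sum(b)
}

zero_phase_filter <- function(x, taps) {
  half <- (length(taps) - 1L) %/% 2L
  n <- length(x)
  # reflection padding keeps constants and ramps exact at the edges
  xp <- c(x[(half + 1L):2L], x, x[(n - 1L):(n - half)])
  y <- stats::filter(xp, taps, sides = 2)
  as.numeric(y)[(half + 1L):(half + n)]
}

#' Differentiate a position trace
#'
#' Two-point central-difference differentiation followed by zero-phase
#' low-pass filtering (FIR, 80 Hz bandwidth, order 50 by default). Endpoints
#' use one-sided differences.
#'
#' @param position Position trace (deg), uniformly sampled.
#' @param fs Sampling rate (Hz), default 1000.
#' @param cutoff_hz Low-pass bandwidth (Hz), default 80.
#' @param order FIR filter order (even), default 50.
#'
#' @return Velocity trace (deg/s), same length as `position`.
#' @export
#' @examples
#' v <- differentiate_trace(seq(0, 10, length.out = 200))  # a ramp
differentiate_trace <- function(position, fs = 1000, cutoff_hz = 80,
                                order = 50) {
  n <- length(position)
  if (n <= order + 1L)
    stop("trace shorter than the filter order; cannot differentiate")
  dt <- 1 / fs
  v <- c(position[2L] - position[1L],
         (position[3L:n] - position[1L:(n - 2L)]) / 2,
         position[n] - position[n - 1L]) / dt
  zero_phase_filter(v, lowpass_taps(order, cutoff_hz, fs))
}

#' Detect saccadic gaze shifts in a trial
#'
#' Events are intervals in which the vectorial gaze speed
#' \eqn{\sqrt{\dot g_H^2 + \dot g_V^2}} stays above the offset threshold and
#' reaches the onset threshold at least once, lasting at least `min_duration`.
#' The criteria are standard saccade-detection practice and configurable.
#'
#' @param trial An [sc_trial()] object.
#' @param onset_threshold Speed the event must reach (deg/s), default 30.
#' @param offset_threshold Speed bounding the event (deg/s), default 20.
#' @param min_duration Minimum event duration (ms), default 15.
#' @param fs Sampling rate (Hz), default 1000.
#'
#' @return A data.frame with one row per event (time order), columns
#'   `onset_ms`, `offset_ms`, `duration_ms`. Zero rows when nothing crosses
#'   the thresholds.
#' @seealso [event_metrics()] to complete the kinematic description,
#'   [primary_gaze_shift()] for the largest event.
#' @export
detect_gaze_shift <- function(trial, onset_threshold = 30,
                              offset_threshold = 20, min_duration = 15,
                              fs = 1000) {
  stopifnot(inherits(trial, "sc_trial"))
  vh <- differentiate_trace(trial$gaze_h, fs)
  vv <- differentiate_trace(trial$gaze_v, fs)
  speed <- sqrt(vh^2 + vv^2)
  above <- speed > offset_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- list()
  for (k in keep) {
    i0 <- starts[k]; i1 <- ends[k]
    if (trial$t[i1] - trial$t[i0] < min_duration) next
    if (max(speed[i0:i1]) < onset_threshold) next
    out[[length(out) + 1L]] <- c(trial$t[i0], trial$t[i1])
  }
  if (!length(out))
    return(data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      duration_ms = numeric(0)))
  m <- do.call(rbind, out)
  data.frame(onset_ms = m[, 1], offset_ms = m[, 2],
             duration_ms = m[, 2] - m[, 1])
}

#' The main gaze shift of a trial
#'
#' Detects gaze shifts and returns the completed event with the largest
#' amplitude (see [event_metrics()]), or `NULL` when none is found.
#'
#' @inheritParams detect_gaze_shift
#' @param ... Passed on to [detect_gaze_shift()].
#' @return A one-row data.frame (completed event) or `NULL`.
#' @export
primary_gaze_shift <- function(trial, ...) {
  ev <- detect_gaze_shift(trial, ...)
  if (!nrow(ev)) return(NULL)
  done <- do.call(rbind, lapply(seq_len(nrow(ev)), function(i)
    event_metrics(trial, ev[i, ])))
  done[which.max(done$dG), , drop = FALSE]
}

trial_index <- function(trial, t_ms) {
  i <- which.min(abs(trial$t - t_ms))
  i
}

#' Straight-line gaze displacement of an event
#'
#' Projects the instantaneous (possibly curved) gaze trajectory, re-referenced
#' to the gaze position at event onset, onto the overall gaze-shift direction
#' \eqn{\Phi = \mathrm{atan2}(\Delta G_V, \Delta G_H)}:
#' \deqn{\Delta g(t) = g_H(t) \cos\Phi + g_V(t) \sin\Phi.}
#' By construction \eqn{\Delta g} is 0 at onset and equals the gaze-shift
#' amplitude \eqn{\Delta G} at offset. Its zero-phase filtered derivative is
#' the straight-line gaze velocity.
#'
#' @param trial An [sc_trial()] object.
#' @param event A one-row data.frame with `onset_ms` and `offset_ms`.
#' @param fs Sampling rate (Hz), default 1000.
#'
#' @return A list: `t` (ms, full trial grid), `dg` (deg), `gdot_lin` (deg/s),
#'   `phi` (deg), `dG` (deg), and the onset/offset indices `i_on`, `i_off`.
#' @export
straight_line_displacement <- function(trial, event, fs = 1000) {
  stopifnot(inherits(trial, "sc_trial"))
  i_on <- trial_index(trial, event$onset_ms)
  i_off <- trial_index(trial, event$offset_ms)
  if (i_off <= i_on) stop("event offset must lie after onset")
  gh <- trial$gaze_h - trial$gaze_h[i_on]
  gv <- trial$gaze_v - trial$gaze_v[i_on]
  dGh <- gh[i_off]; dGv <- gv[i_off]
  dG <- sqrt(dGh^2 + dGv^2)
  if (dG == 0) stop("zero-amplitude gaze shift: direction undefined")
  phi <- atan2(dGv, dGh)
  dg <- gh * cos(phi) + gv * sin(phi)
  list(t = trial$t, dg = dg, gdot_lin = differentiate_trace(dg, fs),
       phi = phi * 180 / pi, dG = dG, i_on = i_on, i_off = i_off)
}

#' Complete the kinematic metrics of a gaze-shift event
#'
#' Fills in the gaze-shift vector (components, amplitude `dG`, direction
#' `phi`), the peak vectorial gaze velocity and its time, the head-movement
#' contribution `dH` during the event, and the initial eye-in-head position.
#' The head contribution is, by default, the head displacement between onset
#' and offset projected onto the gaze-shift direction; the vectorial head
#' displacement is available as an option.
#'
#' @param trial An [sc_trial()] object.
#' @param event A one-row data.frame with at least `onset_ms`, `offset_ms`.
#' @param head_contribution `"projected"` (default) or `"vectorial"`.
#' @param fs Sampling rate (Hz), default 1000.
#'
#' @return The event as a one-row data.frame with columns `onset_ms`,
#'   `offset_ms`, `duration_ms`, `dG_h`, `dG_v`, `dG`, `phi` (deg),
#'   `peak_velocity` (deg/s), `peak_velocity_time` (ms), `dH` (deg), `E0`.
#' @export
event_metrics <- function(trial, event,
                          head_contribution = c("projected", "vectorial"),
                          fs = 1000) {
  head_contribution <- match.arg(head_contribution)
  i_on <- trial_index(trial, event$onset_ms)
  i_off <- trial_index(trial, event$offset_ms)
  if (i_off <= i_on) stop("event offset must lie after onset")
  dGh <- trial$gaze_h[i_off] - trial$gaze_h[i_on]
  dGv <- trial$gaze_v[i_off] - trial$gaze_v[i_on]
  dG <- sqrt(dGh^2 + dGv^2)
  phi <- atan2(dGv, dGh)
  vh <- differentiate_trace(trial$gaze_h, fs)
  vv <- differentiate_trace(trial$gaze_v, fs)
  speed <- sqrt(vh^2 + vv^2)[i_on:i_off]
  ipk <- which.max(speed)           # ties: earliest sample
  dHh <- trial$head_h[i_off] - trial$head_h[i_on]
  dHv <- trial$head_v[i_off] - trial$head_v[i_on]
  dH <- if (head_contribution == "projected")
    dHh * cos(phi) + dHv * sin(phi) else sqrt(dHh^2 + dHv^2)
  data.frame(onset_ms = trial$t[i_on], offset_ms = trial$t[i_off],
             duration_ms = trial$t[i_off] - trial$t[i_on],
             dG_h = dGh, dG_v = dGv, dG = dG, phi = phi * 180 / pi,
             peak_velocity = max(speed),
             peak_velocity_time = trial$t[i_on + ipk - 1L],
             dH = dH, E0 = trial$E0)
}
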