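b64_encode_dbl <- function(x)
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8,
                                endian = "little"))

b64_decode_dbl <- function(s) {
  r <- jsonlite::base64_dec(s)
  readBin(r, "numeric", n = length(r) %/% 8, size = 8, endian = "little")
}

config_to_list <- function(config) {
  list(map = unclass(config$map), mf = unclass(config$mf),
       noise = unclass(config$noise), n_pop = config$n_pop,
       pop_sigma = config$pop_sigma, B = config$B, delta_T = config$delta_T,
       theta_fixed = config$theta_fixed, kin = config$kin,
       head = config$head, E0_levels = config$E0_levels,
       n_trials = config$n_trials, target_spread = config$target_spread,
       spike_mode = config$spike_mode, seed = config$seed)
}

config_from_list <- function(x) {
  sim_config(map = do.call(map_params, x$map),
             mf = do.call(mf_params, x$mf),
             noise = noise_params(x$noise$c_v, x$noise$sigma_add),
             n_pop = x$n_pop, pop_sigma = x$pop_sigma, B = x$B,
             delta_T = x$delta_T, theta_fixed = x$theta_fixed,
             kin = x$kin, head = x$head, E0_levels = unlist(x$E0_levels),
             n_trials = x$n_trials, target_spread = x$target_spread,
             spike_mode = x$spike_mode, seed = x$seed)
}

#' Write a session to a plain-text file
#'
#' Serializes a recording/simulation session to a versioned JSON layout.
#' Float64 traces and spike times are base64-encoded so that the round trip
#' through [read_session()] is lossless (bit-exact), while the file stays
#' plain text.
#'
#' @param session An `"sc_session"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "sc_session"))
  trials <- lapply(session$trials, function(tr) {
    list(trial_id = tr$trial_id, E0 = tr$E0, H0 = tr$H0,
         target = tr$target, t0 = tr$t[1], dt = diff(tr$t)[1],
         n = length(tr$t),
         gaze_h = b64_encode_dbl(tr$gaze_h), gaze_v = b64_encode_dbl(tr$gaze_v),
         head_h = b64_encode_dbl(tr$head_h), head_v = b64_encode_dbl(tr$head_v),
         spikes = b64_encode_dbl(tr$spikes))
  })
  obj <- list(format = "scgaze-session", version = 1L,
              cell = list(mf = unclass(session$cell$mf),
                          map = unclass(session$cell$map),
                          site = as.list(session$cell$site),
                          center_deg = as.list(session$cell$center_deg)),
              config = if (!is.null(session$config))
                config_to_list(session$config),
              trials = trials)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a session from a plain-text file
#'
#' @param path File written by [write_session()].
#' @return An `"sc_session"` object. Files without a stored generator config
#'   load with a warning and `config = NULL`.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop(sprintf("session file '%s' does not exist", path))
  obj <- jsonlite::read_json(path)
  if (is.null(obj$format) || obj$format != "scgaze-session")
    stop("not a session file: missing or wrong 'format' field")
  if (is.null(obj$version) || obj$version != 1L)
    stop(sprintf("unsupported session version '%s'", obj$version))
  if (is.null(obj$trials)) stop("corrupt session file: missing 'trials' group")
  if (is.null(obj$cell)) stop("corrupt session file: missing 'cell' group")
  config <- if (is.null(obj$config)) {
    warning("session file has no generator config; config marked unknown")
    NULL
  } else config_from_list(obj$config)
  cell <- list(mf = do.call(mf_params, obj$cell$mf),
               map = do.call(map_params, obj$cell$map),
               site = unlist(obj$cell$site),
               center_deg = unlist(obj$cell$center_deg))
  trials <- lapply(obj$trials, function(tr) {
    for (f in c("gaze_h", "gaze_v", "head_h", "head_v", "spikes"))
      if (is.null(tr[[f]]))
        stop(sprintf("corrupt session file: trial missing dataset '%s'", f))
    tt <- tr$t0 + tr$dt * (0:(tr$n - 1L))
    sc_trial(tt, b64_decode_dbl(tr$gaze_h), b64_decode_dbl(tr$gaze_v),
             b64_decode_dbl(tr$head_h), b64_decode_dbl(tr$head_v),
             b64_decode_dbl(tr$spikes), E0 = tr$E0, H0 = tr$H0,
             target = unlist(tr$target), trial_id = tr$trial_id)
  })
  structure(list(trials = trials, cell = cell, config = config),
            class = "sc_session")
}

#' Analysis configuration
#'
#' Collects the tunable parameters of the full analysis chain. Defaults
#' mirror the standard settings: 20-ms neural lead, fixed 4-ms spike-density
#' kernel, burst-count inclusion criteria of 10 spikes for phase fits and 15
#' for correlation histograms, 1000 bootstrap resamples, and a 0.005
#' significance level for the one-tailed KS comparison of the original and
#' shuffled correlation distributions.
#'
#' @param lead Neural lead (ms).
#' @param kernel `"fixed"` or `"adaptive"` spike-density kernel.
#' @param sigma Fixed-kernel width (ms).
#' @param min_nspk_phase Burst-count minimum for phase-trajectory fits.
#' @param min_nspk_corr Burst-count minimum for correlation histograms.
#' @param onset_threshold,offset_threshold,min_duration Gaze-shift detection
#'   criteria (deg/s, deg/s, ms).
#' @param cluster_bin,cluster_min_size,cluster_radius Endpoint clustering
#'   settings (deg, count, deg).
#' @param n_boot Bootstrap resamples.
#' @param ks_alpha KS significance level.
#' @param seed Seed consumed by the stochastic stages (shuffle, bootstrap).
#'
#' @return An object of class `"analysis_config"`.
#' @export
analysis_config <- function(lead = 20, kernel = c("fixed", "adaptive"),
                            sigma = 4, min_nspk_phase = 10,
                            min_nspk_corr = 15, onset_threshold = 30,
                            offset_threshold = 20, min_duration = 15,
                            cluster_bin = 2, cluster_min_size = 3,
                            cluster_radius = 10, n_boot = 1000,
                            ks_alpha = 0.005, seed = 1L) {
  kernel <- match.arg(kernel)
  stopifnot(lead >= 0, sigma > 0, min_nspk_phase > 0, min_nspk_corr > 0,
            n_boot > 0, ks_alpha > 0)
  structure(as.list(environment()), class = "analysis_config")
}

run_stage <- function(report, name, expr) {
  res <- tryCatch(expr, error = function(e) {
    warning(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            call. = FALSE)
    structure(list(message = conditionMessage(e)), class = "stage_error")
  })
  report[[name]] <- res
  report
}

stage_ok <- function(x) !is.null(x) && !inherits(x, "stage_error")

#' Run the full analysis chain on a session
#'
#' Orchestrates: gaze-shift detection, burst selection, static gain-field
#' fitting, mean-SD (multiplicative-noise) regression, phase-trajectory fits,
#' spike-density/gaze-velocity correlations, the session shuffle null with
#' one-tailed KS comparison and beta-shaped histogram fits, endpoint
#' clustering, peak regressions, the z-score partial regression, and the
#' head-contribution effect. Stage failures are reported per stage without
#' aborting independent downstream stages. Deterministic given
#' `config$seed`.
#'
#' @param session An `"sc_session"` object.
#' @param config An [analysis_config()] object.
#' @return An object of class `"sc_report"`: a list with one element per
#'   stage (`events`, `bursts`, `mf_fit`, `noise_fit`, `phase_fits`,
#'   `correlations`, `shuffle`, `ks`, `beta_fit_null`, `beta_fit_orig`,
#'   `clusters`, `peak_regressions`, `partial_regression`, `head_effect`),
#'   plus `config` and `package_version`. Failed stages hold a
#'   `"stage_error"` with the message.
#' @export
run_full_analysis <- function(session, config = analysis_config()) {
  stopifnot(inherits(session, "sc_session"),
            inherits(config, "analysis_config"))
  if (!length(session$trials)) stop("session has no trials")
  set.seed(config$seed)
  report <- list(config = config,
                 package_version =
                   as.character(utils::packageVersion("scgaze")))

  # --- detection + burst selection ------------------------------------
  per_trial <- list()
  for (tr in session$trials) {
    ev <- primary_gaze_shift(tr, onset_threshold = config$onset_threshold,
                             offset_threshold = config$offset_threshold,
                             min_duration = config$min_duration)
    if (is.null(ev)) next
    burst <- select_burst_spikes(tr$spikes, ev, lead = config$lead)
    per_trial[[length(per_trial) + 1L]] <-
      list(trial = tr, event = cbind(trial_id = tr$trial_id, ev),
           burst = burst)
  }
  if (!length(per_trial)) stop("no detectable gaze shift in any trial")
  events <- do.call(rbind, lapply(per_trial, `[[`, "event"))
  report$events <- events
  report$bursts <- data.frame(trial_id = events$trial_id,
                              n_spk = vapply(per_trial,
                                             function(p) p$burst$n_spk,
                                             integer(1)))

  # --- static movement field + count-noise regression -----------------
  mf_data <- data.frame(dG = events$dG, phi = events$phi, E0 = events$E0,
                        n_spk = report$bursts$n_spk)
  report <- run_stage(report, "mf_fit",
                      fit_static_field(mf_data, session$cell$map))
  report <- run_stage(report, "noise_fit", {
    if (!stage_ok(report$mf_fit)) stop("static fit unavailable")
    noise_regression(report$mf_fit$fitted, mf_data$n_spk)
  })

  # --- per-trial dynamics ---------------------------------------------
  fitted_mf <- if (stage_ok(report$mf_fit)) report$mf_fit$params else
    session$cell$mf
  phase_rows <- list(); corr_rows <- list()
  sd_prof <- list(); vel_prof <- list()
  for (p in per_trial) {
    if (p$burst$n_spk < 1L) next
    dens <- if (config$kernel == "fixed")
      spike_density_fixed(p$burst, sigma = config$sigma)
    else spike_density_adaptive(p$burst)
    sld <- straight_line_displacement(p$trial, p$event)
    rec <- sd_velocity_correlation(dens, sld, p$event, lead = config$lead,
                                   trial_id = p$trial$trial_id)
    corr_rows[[length(corr_rows) + 1L]] <- rec
    idx <- sld$i_on:sld$i_off
    sd_prof[[length(sd_prof) + 1L]] <-
      density_at(dens, sld$t[idx] - config$lead, "sd")
    vel_prof[[length(vel_prof) + 1L]] <- sld$gdot_lin[idx]
    if (p$burst$n_spk >= config$min_nspk_phase) {
      traj <- phase_trajectory(p$trial, p$event, dens, lead = config$lead)
      pf <- phase_fit_and_deviation(traj, min_spikes = config$min_nspk_phase)
      n_stmf <- predict_static_count(p$event$dG, p$event$phi, p$event$E0,
                                     fitted_mf, session$cell$map)
      phase_rows[[length(phase_rows) + 1L]] <-
        data.frame(trial_id = p$trial$trial_id, a = pf$a, b = pf$b,
                   dev_sd = pf$dev_sd, alpha_pred = n_stmf / p$event$dG,
                   n_spk = pf$n_spk, dG = pf$dG)
    }
  }
  report$phase_fits <- if (length(phase_rows)) do.call(rbind, phase_rows)
  else {
    warning("no burst reached the phase-fit spike criterion")
    data.frame(trial_id = integer(0), a = numeric(0), b = numeric(0),
               dev_sd = numeric(0), alpha_pred = numeric(0),
               n_spk = integer(0), dG = numeric(0))
  }
  correlations <- if (length(corr_rows)) do.call(rbind, corr_rows)
  else data.frame()
  report$correlations <- correlations

  # --- shuffle null, KS, beta fits ------------------------------------
  keep <- which(!correlations$flagged &
                  correlations$n_spk >= config$min_nspk_corr)
  report <- run_stage(report, "shuffle", {
    if (length(keep) < 2L) stop("too few qualifying trials for the shuffle")
    shuffle_null(sd_prof[keep], vel_prof[keep])
  })
  report <- run_stage(report, "ks", {
    if (!stage_ok(report$shuffle)) stop("shuffle null unavailable")
    ks_one_tailed(correlations$r[keep], report$shuffle,
                  alpha = config$ks_alpha)
  })
  report <- run_stage(report, "beta_fit_null", {
    if (!stage_ok(report$shuffle)) stop("shuffle null unavailable")
    fit_beta_distribution(report$shuffle)
  })
  report <- run_stage(report, "beta_fit_orig",
                      fit_beta_distribution(correlations$r[keep]))

  # --- clusters, peak and partial regressions, head effect ------------
  ctr <- efferent_map(fitted_mf$u0, fitted_mf$v0, session$cell$map)
  center_xy <- ctr$dG * c(cos(ctr$phi * pi / 180), sin(ctr$phi * pi / 180))
  report <- run_stage(report, "clusters",
                      cluster_gaze_shifts(events, center_xy,
                                          bin = config$cluster_bin,
                                          min_size = config$cluster_min_size,
                                          radius = config$cluster_radius))
  report <- run_stage(report, "peak_regressions", {
    rec <- correlations[correlations$n_spk >= config$min_nspk_corr, ]
    if (stage_ok(report$clusters)) {
      in_cl <- report$clusters$events$trial_id[
        !is.na(report$clusters$events$cluster)]
      if (sum(rec$trial_id %in% in_cl) >= 10L)
        rec <- rec[rec$trial_id %in% in_cl, ]
    }
    peak_regressions(rec, n_boot = config$n_boot)
  })
  report <- run_stage(report, "partial_regression", {
    rec <- correlations[correlations$n_spk >= config$min_nspk_corr, ]
    zscore_partial_regression(rec$peak_velocity, rec$peak_sd, rec$n_spk,
                              n_boot = config$n_boot)
  })
  report <- run_stage(report, "head_effect",
                      head_amplitude_effect(correlations,
                                            min_nspk = config$min_nspk_corr))
  class(report) <- "sc_report"
  report
}

#' @export
print.sc_report <- function(x, ...) {
  cat(sprintf("Analysis report (scgaze %s)\n", x$package_version))
  cat(sprintf("  %d events, %d phase fits, %d correlation records\n",
              nrow(x$events), nrow(x$phase_fits), nrow(x$correlations)))
  if (stage_ok(x$mf_fit)) {
    cat("  static field: "); print(x$mf_fit$params)
    cat(sprintf("    fit r = %.3f\n", x$mf_fit$r))
  }
  if (stage_ok(x$noise_fit))
    cat(sprintf("  count noise: slope C_V = %.3f, offset = %.2f spikes (r = %.2f)\n",
                x$noise_fit$slope, x$noise_fit$offset, x$noise_fit$r))
  if (stage_ok(x$ks))
    cat(sprintf("  original vs shuffled correlations: KS D = %.3f, p = %.2g\n",
                x$ks$statistic, x$ks$p_value))
  invisible(x)
}

#' Write the report tables to a directory
#'
#' Emits `events.csv`, `bursts.csv`, `phase_fits.csv`, `correlations.csv`,
#' `mf_fit.json`, `noise_fit.json`, `beta_fit.json` and `summary.json` under
#' `out_dir`. Failed stages are skipped.
#'
#' @param report An `"sc_report"` from [run_full_analysis()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "sc_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, f) utils::write.csv(df, file.path(out_dir, f),
                                           row.names = FALSE)
  wcsv(report$events, "events.csv")
  wcsv(report$bursts, "bursts.csv")
  wcsv(report$phase_fits, "phase_fits.csv")
  wcsv(report$correlations, "correlations.csv")
  if (stage_ok(report$mf_fit))
    jsonlite::write_json(
      c(unclass(report$mf_fit$params),
        list(r = report$mf_fit$r, n_trials = report$mf_fit$n_trials)),
      file.path(out_dir, "mf_fit.json"), auto_unbox = TRUE, digits = NA)
  if (stage_ok(report$noise_fit))
    jsonlite::write_json(report$noise_fit[c("offset", "slope", "r")],
                         file.path(out_dir, "noise_fit.json"),
                         auto_unbox = TRUE, digits = NA)
  if (stage_ok(report$beta_fit_null))
    jsonlite::write_json(
      report$beta_fit_null[c("P0", "alpha", "beta", "mode_r", "n")],
      file.path(out_dir, "beta_fit.json"), auto_unbox = TRUE, digits = NA)
  summary <- list(package_version = report$package_version,
                  n_events = nrow(report$events),
                  ks = if (stage_ok(report$ks)) report$ks)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
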