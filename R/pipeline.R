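#' Full analysis of one MEA recording
#'
#' Runs the complete pipeline on a raw recording and returns every metric in
#' one object:
#' \enumerate{
#'   \item Savitzky-Golay smoothing of the raw signal.
#'   \item Spike stage: zero-phase band-pass (300 Hz up to 2500 Hz or just
#'     below Nyquist), threshold detection (4 baseline SDs, baseline on the
#'     first 30 s), active-electrode classification (> 12 spikes/min), burst
#'     detection (>= 4 spikes / 100 ms) and per-channel firing statistics.
#'   \item Network stage, on a randomly placed 60 s window: spike-count
#'     correlation (50 ms bins), connectivity graph (r > 0.5), network
#'     spiking percentage (100 ms bins) and its periodicity by
#'     autocorrelation and Welch periodogram.
#'   \item Oscillation stage: decimation to 1000 Hz, synchrosqueezed
#'     band decomposition, relative band power (Welch 2000/1000 ms), LFP
#'     peak amplitude, and the phase-amplitude coupling panel
#'     (delta/theta phase vs low/upper gamma amplitude).
#' }
#'
#' @param rec a raw [mea_recording()].
#' @param recording_id label used in the metric table.
#' @param window_s network analysis window (default 60 s).
#' @param seed seed for the analysis-window draw.
#' @param sd_multiplier,baseline_window_s spike-detection settings.
#' @param corr_bin_ms,corr_threshold connectivity settings.
#' @param bands band table.
#' @param lfp_fs_hz LFP sampling rate (default 1000; must divide the
#'   recording rate).
#' @param savgol apply the Savitzky-Golay prefilter (default TRUE).
#' @return an `mea_analysis` object: list with `metrics` (tidy metric
#'   table), `channel_stats`, `trains`, `bursts`, `graph`, `periodicity`,
#'   `band_power`, `pac`, `active`, `lfp_peak`, `window`.
#' @export
analyze_recording <- function(rec, recording_id = "rec", window_s = 60,
                              seed = NULL, sd_multiplier = 4,
                              baseline_window_s = 30, corr_bin_ms = 50,
                              corr_threshold = 0.5, bands = mea_bands(),
                              lfp_fs_hz = 1000, savgol = TRUE) {
  stopifnot(inherits(rec, "mea_recording"))
  # Savitzky-Golay window scaled to a fixed time span (9 points at 25 kHz,
  # ~0.36 ms) so lower sampling rates are not over-smoothed
  sg_win <- max(5L, round(9 * rec$fs_hz / 25000) %/% 2L * 2L + 1L)
  sm <- if (savgol) savgol_smooth(rec, window_points = sg_win) else rec

  # ---- spike stage --------------------------------------------------
  hi <- min(2500, 0.45 * rec$fs_hz)
  spk <- spike_band_filter(sm, low_hz = 300, high_hz = hi)
  win <- select_analysis_window(spk, window_s = min(window_s, rec_duration(spk)),
                                seed = seed)
  dur <- rec_duration(win)
  trains <- detect_spikes(win, sd_multiplier = sd_multiplier,
                          baseline_window_s = min(baseline_window_s, dur))
  bursts <- lapply(trains, detect_bursts)
  stats_df <- do.call(rbind, Map(channel_stats, trains, bursts,
                                 MoreArgs = list(duration_s = dur)))
  active <- stats_df$channel_id[stats_df$active]

  # ---- network stage ------------------------------------------------
  act_trains <- trains[match(active, vapply(trains, `[[`, "", "channel_id"))]
  graph <- NULL; per <- NULL
  if (length(act_trains) >= 2) {
    cm <- spike_correlation_matrix(act_trains, bin_ms = corr_bin_ms,
                                   t_start_s = win$t0_s, duration_s = dur)
    graph <- connectivity_graph(cm, threshold = corr_threshold)
  }
  if (length(act_trains) >= 1) {
    nsp <- network_spiking_percentage(act_trains, bin_ms = 100,
                                      t_start_s = win$t0_s, duration_s = dur)
    per <- periodicity(nsp$series, nsp$fs_hz)
  }

  # ---- oscillation stage --------------------------------------------
  lfp_src <- rec_slice(sm, win$t0_s, dur)
  lfp <- lfp_downsample(lfp_src, target_fs_hz = lfp_fs_hz)
  band_sig <- sst_band_decompose(lfp, bands = bands)
  bp <- relative_band_power(band_sig, bands = bands)
  peak <- lfp_peak_amplitude(lfp)
  pac <- pac_panel(lfp, bands = bands)

  # ---- metric table -------------------------------------------------
  rows <- list(
    data.frame(recording_id = recording_id, channel_id = stats_df$channel_id,
               metric_name = "spike_rate", value = stats_df$spike_rate_hz),
    data.frame(recording_id = recording_id, channel_id = stats_df$channel_id,
               metric_name = "burst_rate", value = stats_df$burst_rate_per_min),
    data.frame(recording_id = recording_id, channel_id = stats_df$channel_id,
               metric_name = "isi_cv", value = stats_df$isi_cv),
    data.frame(recording_id = recording_id, channel_id = rec$channel_ids,
               metric_name = "lfp_peak_amp", value = unname(peak))
  )
  for (b in bands$name)
    rows[[length(rows) + 1L]] <-
      data.frame(recording_id = recording_id, channel_id = rec$channel_ids,
                 metric_name = paste0("relpow_", b),
                 value = unname(bp$rel_power[, b]))
  rows[[length(rows) + 1L]] <-
    data.frame(recording_id = recording_id, channel_id = pac$channel_id,
               metric_name = pac$metric, value = pac$mi)
  if (!is.null(graph)) {
    rows[[length(rows) + 1L]] <-
      data.frame(recording_id = recording_id, channel_id = "ALL",
                 metric_name = c("pct_connected", "weight"),
                 value = c(graph$percent_connected, graph$mean_weight))
  }
  if (!is.null(per) && per$autocorrelation$detected) {
    rows[[length(rows) + 1L]] <-
      data.frame(recording_id = recording_id, channel_id = "ALL",
                 metric_name = "period_s",
                 value = per$autocorrelation$period_s)
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL

  structure(list(metrics = metrics, channel_stats = stats_df,
                 trains = trains, bursts = bursts, graph = graph,
                 periodicity = per, band_power = bp, pac = pac,
                 active = active, lfp_peak = peak, window = win,
                 recording_id = recording_id),
            class = "mea_analysis")
}

#' @export
print.mea_analysis <- function(x, ...) {
  cat(sprintf("<mea_analysis '%s'> %d/%d channels active\n", x$recording_id,
              length(x$active), nrow(x$channel_stats)))
  if (!is.null(x$graph))
    cat(sprintf("  connectivity: %.1f%% connected, mean weight %.3g\n",
                x$graph$percent_connected, x$graph$mean_weight))
  if (!is.null(x$periodicity)) {
    p <- x$periodicity$autocorrelation
    cat(sprintf("  periodicity (autocorr): %s\n",
                if (p$detected) sprintf("%.2f s", p$period_s) else "none"))
  }
  cat("  relative band power (channel means):\n  ")
  print(round(colMeans(x$band_power$rel_power), 3))
  invisible(x)
}

#' @export
summary.mea_analysis <- function(object, ...) {
  summarize_channels(object$metrics, object$active)
}

#' Analyze a simulated cohort end to end
#'
#' Convenience wrapper: [simulate_cohort()] then [analyze_recording()] and
#' [summarize_channels()] per organoid, returning one organoid-level row per
#' metric per recording plus the group label.
#'
#' @param preset,n_organoids,seed,... forwarded to [simulate_cohort()].
#' @return data.frame of organoid summaries with a `group` column.
#' @export
analyze_cohort <- function(preset, n_organoids, seed = 0L, ...) {
  sims <- simulate_cohort(preset, n_organoids, seed = seed, ...)
  out <- lapply(seq_along(sims), function(i) {
    id <- paste0(preset, "_", i)
    an <- analyze_recording(sims[[i]]$recording, recording_id = id,
                            seed = seed + i)
    s <- summarize_channels(an$metrics, an$active)
    s$group <- preset
    s
  })
  do.call(rbind, out)
}
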