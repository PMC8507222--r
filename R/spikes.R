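#' Threshold spike detection on a band-passed recording
#'
#' Detects multi-unit spikes per channel as local extrema of the absolute
#' deviation from the baseline mean exceeding `sd_multiplier` baseline
#' standard deviations. Baseline mean and SD are estimated per electrode on
#' the first `baseline_window_s` seconds of the recording. Both polarities
#' trigger (extracellular spikes are predominantly negative, but the rule is
#' applied to |x - mean|). Successive events are separated by at least
#' `refractory_ms`, keeping the largest peak of each conflicting cluster: a
#' band-passed spike is necessarily zero-mean and so carries rebound lobes of
#' roughly a third of its peak about 1 ms to either side, so the dead time
#' must cover them (hence the 2 ms default) and amplitude priority ensures
#' the true peak, not a leading rebound, is the reported event.
#'
#' @param rec a spike-band-filtered [mea_recording()].
#' @param sd_multiplier detection threshold in baseline SDs (default 4).
#' @param baseline_window_s baseline estimation window (default 30 s); the
#'   recording must be at least this long.
#' @param refractory_ms minimum separation between events (default 2 ms).
#' @return a list of `mea_spike_train` objects, one per channel, each with
#'   `channel_id`, `times_s` (strictly increasing), `threshold_v`
#'   (`baseline_mean_v + sd_multiplier * baseline_sd_v`), `baseline_mean_v`,
#'   `baseline_sd_v` and a `degenerate` flag (TRUE when the baseline SD is
#'   zero, in which case the train is empty rather than an error).
#' @export
detect_spikes <- function(rec, sd_multiplier = 4, baseline_window_s = 30,
                          refractory_ms = 2) {
  stopifnot(inherits(rec, "mea_recording"))
  if (rec_duration(rec) < baseline_window_s)
    stop("recording (", rec_duration(rec), " s) shorter than baseline window (",
         baseline_window_s, " s)")
  nb <- round(baseline_window_s * rec$fs_hz)
  refr <- refractory_ms / 1000
  lapply(seq_len(nrow(rec$data)), function(ch) {
    x <- rec$data[ch, ]
    mu <- mean(x[seq_len(nb)])
    sd0 <- stats::sd(x[seq_len(nb)])
    if (!is.finite(sd0) || sd0 == 0) {
      return(structure(list(channel_id = rec$channel_ids[ch],
                            times_s = numeric(0),
                            threshold_v = NA_real_, baseline_mean_v = mu,
                            baseline_sd_v = sd0, degenerate = TRUE),
                       class = "mea_spike_train"))
    }
    dev <- abs(x - mu)
    thr <- sd_multiplier * sd0
    n <- length(dev)
    # local maxima of the deviation that exceed the threshold
    cand <- which(dev > thr)
    cand <- cand[cand > 1L & cand < n]
    cand <- cand[dev[cand] >= dev[cand - 1L] & dev[cand] > dev[cand + 1L]]
    times <- (cand - 1L) / rec$fs_hz + rec$t0_s
    if (length(times) > 1L) {
      # amplitude-priority refractory: accept peaks from largest downward,
      # rejecting any within `refr` of an already-accepted event
      ord <- order(dev[cand], decreasing = TRUE)
      kept <- numeric(0)
      for (i in ord) {
        if (!length(kept) || min(abs(kept - times[i])) >= refr)
          kept <- c(kept, times[i])
      }
      times <- sort(kept)
    }
    structure(list(channel_id = rec$channel_ids[ch], times_s = times,
                   threshold_v = mu + sd_multiplier * sd0,
                   baseline_mean_v = mu, baseline_sd_v = sd0,
                   degenerate = FALSE),
              class = "mea_spike_train")
  })
}

#' @export
print.mea_spike_train <- function(x, ...) {
  cat(sprintf("<mea_spike_train> %s: %d spikes%s\n", x$channel_id,
              length(x$times_s), if (isTRUE(x$degenerate)) " (degenerate baseline)" else ""))
  invisible(x)
}

#' Active-electrode classification
#'
#' An electrode is active when it fires strictly more than `min_rate_per_min`
#' spikes per minute; electrodes at or below the cutoff (default 12/min) are
#' inactive and are excluded from organoid-level averages.
#'
#' @param train an `mea_spike_train` (or anything with `times_s`).
#' @param duration_s recording duration in seconds (> 0).
#' @param min_rate_per_min inactivity cutoff in spikes per minute (default 12).
#' @return logical.
#' @export
classify_active <- function(train, duration_s, min_rate_per_min = 12) {
  if (duration_s <= 0) stop("`duration_s` must be positive")
  length(train$times_s) / duration_s * 60 > min_rate_per_min
}

#' Burst detection: at least `min_spikes` spikes within `window_ms`
#'
#' A burst exists wherever some `window_ms` window contains at least
#' `min_spikes` spikes (defaults: 4 spikes in 100 ms). Overlapping qualifying
#' windows — windows sharing at least one spike — are merged into a single
#' burst spanning its first to last member spike, so one prolonged burst is
#' never double-counted.
#'
#' @param train an `mea_spike_train` (sorted times).
#' @param min_spikes minimum spikes per window (default 4).
#' @param window_ms window length in milliseconds (default 100).
#' @return an `mea_burst_set`: `channel_id`, `intervals` (two-column matrix
#'   of start/end seconds, disjoint and sorted), `spike_counts`.
#' @export
detect_bursts <- function(train, min_spikes = 4, window_ms = 100) {
  t <- train$times_s
  n <- length(t)
  w <- window_ms / 1000
  empty <- structure(list(channel_id = train$channel_id,
                          intervals = matrix(numeric(0), ncol = 2,
                                             dimnames = list(NULL, c("start_s", "end_s"))),
                          spike_counts = integer(0)),
                     class = "mea_burst_set")
  if (n < min_spikes) return(empty)
  # last spike index inside [t_i, t_i + w] for each i
  j <- findInterval(t + w, t)
  qual <- which(j - seq_len(n) + 1L >= min_spikes)
  if (length(qual) == 0L) return(empty)
  # merge qualifying index spans [i, j_i] that share spikes
  starts <- integer(0); ends <- integer(0)
  cur_s <- qual[1L]; cur_e <- j[qual[1L]]
  for (i in qual[-1L]) {
    if (i <= cur_e) cur_e <- max(cur_e, j[i])
    else { starts <- c(starts, cur_s); ends <- c(ends, cur_e)
           cur_s <- i; cur_e <- j[i] }
  }
  starts <- c(starts, cur_s); ends <- c(ends, cur_e)
  structure(list(channel_id = train$channel_id,
                 intervals = cbind(start_s = t[starts], end_s = t[ends]),
                 spike_counts = ends - starts + 1L),
            class = "mea_burst_set")
}

#' @export
print.mea_burst_set <- function(x, ...) {
  cat(sprintf("<mea_burst_set> %s: %d bursts\n", x$channel_id,
              nrow(x$intervals)))
  invisible(x)
}

#' Per-channel firing statistics
#'
#' Spike rate (Hz), burst rate (per minute), inter-spike-interval coefficient
#' of variation (SD/mean of successive ISIs; 0 for perfectly periodic firing,
#' about 1 for Poisson firing) and the active flag. The ISI CV is `NA` for
#' trains with fewer than 3 spikes.
#'
#' @param train an `mea_spike_train`.
#' @param bursts the channel's `mea_burst_set` (or NULL for none).
#' @param duration_s recording duration in seconds (> 0).
#' @return a one-row data.frame: `channel_id`, `spike_rate_hz`,
#'   `burst_rate_per_min`, `isi_cv`, `active`, `degenerate`.
#' @export
channel_stats <- function(train, bursts = NULL, duration_s) {
  if (duration_s <= 0) stop("`duration_s` must be positive")
  n <- length(train$times_s)
  nb <- if (is.null(bursts)) 0L else nrow(bursts$intervals)
  isi_cv <- NA_real_
  if (n >= 3) {
    isi <- diff(train$times_s)
    isi_cv <- stats::sd(isi) / mean(isi)
  }
  data.frame(channel_id = train$channel_id,
             spike_rate_hz = n / duration_s,
             burst_rate_per_min = nb / duration_s * 60,
             isi_cv = isi_cv,
             active = classify_active(train, duration_s),
             degenerate = isTRUE(train$degenerate),
             stringsAsFactors = FALSE)
}
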