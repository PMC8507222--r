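# Independent oracles used across test files.

# Exhaustive O(n^2) burst oracle: enumerate every spike pair (i, j) with
# t_j - t_i <= window and j - i + 1 >= min_spikes, mark the index span, and
# merge spans that share spikes. Independent of the findInterval route used
# by detect_bursts().
oracle_bursts <- function(times, min_spikes = 4, window_ms = 100) {
  n <- length(times)
  w <- window_ms / 1000
  spans <- list()
  if (n >= min_spikes) {
    for (i in seq_len(n)) {
      for (j in i:n) {
        if (times[j] - times[i] > w) break
        if (j - i + 1 >= min_spikes) spans[[length(spans) + 1L]] <- c(i, j)
      }
    }
  }
  if (length(spans) == 0)
    return(list(intervals = matrix(numeric(0), ncol = 2), counts = integer(0)))
  m <- do.call(rbind, spans)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  if (nrow(m) > 1) {
    for (k in 2:nrow(m)) {
      if (m[k, 1] <= out[nrow(out), 2])
        out[nrow(out), 2] <- max(out[nrow(out), 2], m[k, 2])
      else out <- rbind(out, m[k, , drop = FALSE])
    }
  }
  list(intervals = cbind(times[out[, 1]], times[out[, 2]]),
       counts = out[, 2] - out[, 1] + 1L)
}

# Direct histogram-binning modulation index, written independently of
# modulation_index(): cut() based binning, entropy over non-empty bins.
oracle_mi <- function(phase, amplitude, n_bins = 18) {
  br <- seq(-pi, pi, length.out = n_bins + 1)
  bin <- cut(phase, breaks = br, include.lowest = TRUE, labels = FALSE)
  means <- rep(0, n_bins)
  agg <- tapply(amplitude, bin, mean)
  means[as.integer(names(agg))] <- agg
  P <- means / sum(means)
  P <- P[P > 0]
  (log(n_bins) + sum(P * log(P))) / log(n_bins)
}

# fraction of ground-truth spikes matched by detections within tol_s
match_fraction <- function(truth_times, det_times, tol_s = 0.0010001) {
  if (length(truth_times) == 0) return(NA_real_)
  mean(vapply(truth_times,
              function(x) any(abs(det_times - x) <= tol_s), logical(1)))
}

unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1], d))
}

# quick synthetic sinusoid recording
tone_recording <- function(freq_hz, fs_hz, duration_s, amplitude = 1,
                           n_channels = 1) {
  tt <- seq_len(round(duration_s * fs_hz)) / fs_hz
  x <- amplitude * sin(2 * pi * freq_hz * tt)
  mea_recording(matrix(rep(x, each = n_channels), nrow = n_channels), fs_hz)
}
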