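#' Select the one-minute analysis window
#'
#' Network metrics are computed on a single contiguous window (default 60 s)
#' whose start is drawn uniformly over the recording; a fixed `seed` makes
#' the draw reproducible. A recording exactly as long as the window is
#' returned whole.
#'
#' @param rec an [mea_recording()].
#' @param window_s window length in seconds (default 60).
#' @param seed optional integer seed for the uniform start draw.
#' @return an `mea_recording` slice of length `window_s`.
#' @export
select_analysis_window <- function(rec, window_s = 60, seed = NULL) {
  stopifnot(inherits(rec, "mea_recording"))
  dur <- rec_duration(rec)
  if (dur < window_s)
    stop("recording (", dur, " s) shorter than analysis window (", window_s, " s)")
  if (dur == window_s) return(rec)
  start <- with_local_seed(seed, stats::runif(1, 0, dur - window_s))
  rec_slice(rec, rec$t0_s + start, window_s)
}

# Binned spike counts: channels x bins matrix over [t_start, t_start + dur)
bin_spike_counts <- function(trains, bin_ms, t_start_s, duration_s) {
  nbins <- ceiling(duration_s * 1000 / bin_ms)
  edges <- t_start_s + seq(0, nbins) * bin_ms / 1000
  counts <- t(vapply(trains, function(tr) {
    tt <- tr$times_s[tr$times_s >= edges[1] & tr$times_s < edges[nbins + 1]]
    tabulate(findInterval(tt, edges), nbins)
  }, numeric(nbins)))
  rownames(counts) <- vapply(trains, `[[`, "", "channel_id")
  counts
}

#' Spike-count correlation matrix
#'
#' Pearson correlation of binned spike counts (default 50 ms bins) between
#' channels over the analysis window. Channels whose binned counts have zero
#' variance yield `NA` entries (flagged, excluded from graphs downstream).
#'
#' @param trains list of `mea_spike_train` (typically active channels only).
#' @param bin_ms bin width in milliseconds (default 50).
#' @param t_start_s,duration_s the analysis window.
#' @return symmetric correlation matrix with unit diagonal, dimnames =
#'   channel ids; entries in \[-1, 1\] or `NA`.
#' @export
spike_correlation_matrix <- function(trains, bin_ms = 50, t_start_s, duration_s) {
  if (length(trains) < 2)
    stop("need at least 2 spike trains")
  counts <- bin_spike_counts(trains, bin_ms, t_start_s, duration_s)
  r <- suppressWarnings(stats::cor(t(counts)))
  diag(r) <- 1
  r
}

#' Threshold a correlation matrix into a connectivity graph
#'
#' Two channels are connected when their coefficient strictly exceeds
#' `threshold` (default 0.5). Reports the percentage of channels with at
#' least one connection and the mean edge weight (the Pearson coefficient).
#'
#' @param corr_matrix square symmetric correlation matrix (NA entries are
#'   treated as unconnectable).
#' @param threshold edge criterion, strict inequality (default 0.5).
#' @param basis label for the correlation basis (default "spike_correlation").
#' @return an `mea_graph`: `nodes`, `edges` (data.frame `a`, `b`, `weight`,
#'   one row per unordered pair), `threshold`, `basis`, `percent_connected`
#'   (0-100), `mean_weight`.
#' @export
connectivity_graph <- function(corr_matrix, threshold = 0.5,
                               basis = "spike_correlation") {
  m <- as.matrix(corr_matrix)
  if (nrow(m) != ncol(m) ||
      !isTRUE(all.equal(m, t(m), tolerance = 1e-8, check.attributes = FALSE)))
    stop("`corr_matrix` must be square and symmetric")
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("ch", seq_len(nrow(m)))
  n <- nrow(m)
  a <- b <- character(0); wgt <- numeric(0)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (!is.na(m[i, j]) && m[i, j] > threshold) {
        a <- c(a, ids[i]); b <- c(b, ids[j]); wgt <- c(wgt, m[i, j])
      }
    }
  }
  edges <- data.frame(a = a, b = b, weight = wgt, stringsAsFactors = FALSE)
  connected <- unique(c(a, b))
  structure(list(nodes = ids, edges = edges, threshold = threshold,
                 basis = basis,
                 percent_connected = if (n) 100 * length(connected) / n else NA_real_,
                 mean_weight = if (nrow(edges)) mean(wgt) else NA_real_),
            class = "mea_graph")
}

#' @export
print.mea_graph <- function(x, ...) {
  cat(sprintf("<mea_graph basis=%s> %d nodes, %d edges (threshold %.3g), %.1f%% connected\n",
              x$basis, length(x$nodes), nrow(x$edges), x$threshold,
              x$percent_connected))
  invisible(x)
}

#' Connectivity from temporally overlapping bursts
#'
#' Two channels are connected when, for either channel, the fraction of its
#' bursts that temporally intersect a burst on the other channel exceeds
#' `min_overlap_fraction`. The edge weight is the larger of the two
#' fractions. Channels without bursts cannot connect.
#'
#' @param burst_sets list of `mea_burst_set` from the same time window.
#' @param min_overlap_fraction edge criterion (default 0.25), strict.
#' @return an `mea_graph` with basis `"overlapping_bursts"`.
#' @export
overlapping_burst_connectivity <- function(burst_sets, min_overlap_fraction = 0.25) {
  ids <- vapply(burst_sets, `[[`, "", "channel_id")
  n <- length(burst_sets)
  frac_overlap <- function(A, B) { # fraction of A's bursts hitting any B burst
    if (nrow(A) == 0) return(NA_real_)
    if (nrow(B) == 0) return(0)
    hits <- vapply(seq_len(nrow(A)), function(k) {
      any(A[k, 1] <= B[, 2] & B[, 1] <= A[k, 2])
    }, logical(1))
    mean(hits)
  }
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(m) <- 1
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      fa <- frac_overlap(burst_sets[[i]]$intervals, burst_sets[[j]]$intervals)
      fb <- frac_overlap(burst_sets[[j]]$intervals, burst_sets[[i]]$intervals)
      m[i, j] <- m[j, i] <- if (is.na(fa) && is.na(fb)) NA_real_
                            else max(fa, fb, na.rm = TRUE)
    }
  }
  connectivity_graph(m, threshold = min_overlap_fraction,
                     basis = "overlapping_bursts")
}

#' Network spiking percentage time series
#'
#' The fraction of the supplied channels that fire at least one spike in
#' each time bin (default 100 ms) — the "network event" series whose
#' periodicity indexes coordinated activity.
#'
#' @param trains list of `mea_spike_train` (use active channels).
#' @param bin_ms bin width in milliseconds (default 100).
#' @param t_start_s,duration_s the analysis window.
#' @return list with `series` (fractions in \[0, 1\], length
#'   `ceiling(duration/bin)`), `fs_hz` (series rate, 1000/bin_ms) and
#'   `t_start_s`.
#' @export
network_spiking_percentage <- function(trains, bin_ms = 100, t_start_s, duration_s) {
  if (length(trains) < 1) stop("need at least one spike train")
  counts <- bin_spike_counts(trains, bin_ms, t_start_s, duration_s)
  list(series = colMeans(counts > 0), fs_hz = 1000 / bin_ms,
       t_start_s = t_start_s)
}

# local maxima indices of a numeric vector (strict on the right)
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  which(v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
}

#' Periodicity of a network-event series
#'
#' Estimates the period of a (spiking-percentage) series by two routes: the
#' normalized autocorrelation and the Welch periodogram. A period is reported
#' only when a suprathreshold peak exists; the detection threshold is the
#' mean + 1 SD of the normalized autocorrelation (resp. power) values over
#' the search range, combined with a white-noise significance guard
#' (family-wise `alpha`, default 0.01) so that an unstructured series yields
#' no detection. Among suprathreshold peaks the one at the smallest lag
#' (lowest frequency) within 50% of the tallest peak is reported, which
#' selects the fundamental of a harmonic comb.
#'
#' The search range is limited to lags 0.5-30 s (0.033-2 Hz) to exclude the
#' trivial lag-0/DC peak; threshold statistics are computed over the same
#' range.
#'
#' @param series numeric vector (e.g. from [network_spiking_percentage()]);
#'   at least 10 points.
#' @param fs_series sampling rate of the series in Hz.
#' @param methods subset of `c("autocorrelation", "welch")`.
#' @param lag_range_s search range in seconds (default `c(0.5, 30)`).
#' @param alpha family-wise false-detection level of the significance guard.
#' @return named list (per method) of `mea_periodicity` objects: `method`,
#'   `period_s` (`NA` when absent), `peak_value`, `detection_threshold`,
#'   `detected`, `flag` (`"zero_variance"` for a constant series).
#' @export
periodicity <- function(series, fs_series,
                        methods = c("autocorrelation", "welch"),
                        lag_range_s = c(0.5, 30), alpha = 0.01) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (length(series) < 10) stop("series must have at least 10 points")
  n <- length(series)
  out <- list()
  res <- function(method, period, peak, thr, detected, flag = NA_character_)
    structure(list(method = method, period_s = period, peak_value = peak,
                   detection_threshold = thr, detected = detected, flag = flag),
              class = "mea_periodicity")
  if (stats::var(series) == 0) {
    for (m in methods) out[[m]] <- res(m, NA_real_, NA_real_, NA_real_,
                                       FALSE, "zero_variance")
    return(out)
  }
  pick_peak <- function(values, axis, thr) {
    pk <- local_maxima(values)
    pk <- pk[values[pk] > thr]
    if (length(pk) == 0) return(NULL)
    best <- max(values[pk])
    pk <- pk[values[pk] >= 0.5 * best]
    i <- pk[which.min(axis[pk])]
    list(pos = axis[i], value = values[i])
  }
  if ("autocorrelation" %in% methods) {
    max_lag <- min(n - 1L, floor(lag_range_s[2] * fs_series))
    ac <- as.numeric(stats::acf(series, lag.max = max_lag, plot = FALSE,
                                demean = TRUE)$acf)
    lags <- (seq_along(ac) - 1L) / fs_series
    sel <- lags >= lag_range_s[1] & lags <= lag_range_s[2]
    vals <- ac[sel]; lsel <- lags[sel]
    m <- length(vals)
    guard <- stats::qnorm(0.5 + 0.5 * (1 - alpha)^(1 / m)) / sqrt(n)
    thr <- max(mean(vals) + stats::sd(vals), guard)
    p <- pick_peak(vals, lsel, thr)
    out$autocorrelation <-
      if (is.null(p)) res("autocorrelation", NA_real_, max(vals), thr, FALSE)
      else res("autocorrelation", p$pos, p$value, thr, TRUE)
  }
  if ("welch" %in% methods) {
    seg_s <- min(n / fs_series / 3, lag_range_s[2])
    ps <- welch_psd(series, fs_series, window_s = seg_s, overlap_s = seg_s / 2,
                    nfft_pad = 16)
    f_lo <- max(1 / lag_range_s[2], ps$df)
    sel <- ps$freq_hz >= f_lo & ps$freq_hz <= 1 / lag_range_s[1]
    vals <- ps$psd[sel]; fsel <- ps$freq_hz[sel]
    f_hi <- max(fsel)
    m_eff <- max(2, floor((f_hi - min(fsel)) / ps$resolution_hz))
    # noise floor from the lower quartile so the comb's own power does not
    # inflate the guard; chi-square dof from the segment count (50%-overlap
    # Hamming segments are mildly correlated, hence the 0.9 deflation)
    k2 <- max(2, round(2 * ps$n_segments * 0.9))
    floor_est <- stats::quantile(vals, 0.25)[[1]] * k2 / stats::qchisq(0.25, k2)
    guard <- floor_est * stats::qchisq((1 - alpha)^(1 / m_eff), k2) / k2
    thr <- max(mean(vals) + stats::sd(vals), guard)
    pk <- local_maxima(vals)
    pk <- pk[vals[pk] > thr]
    out$welch <- if (length(pk) == 0) {
      res("welch", NA_real_, max(vals), thr, FALSE)
    } else {
      # A pulse-train series yields a harmonic comb whose fundamental tooth
      # can be weak relative to its harmonics. Candidate fundamentals are
      # the suprathreshold peaks and their subharmonics; each is scored by
      # the floor-corrected power summed over its harmonics in the search
      # band (harmonic-sum estimate), integrating the comb coherently the
      # way the autocorrelation does. Near-ties resolve to the highest
      # candidate frequency to avoid subharmonic aliases.
      fpk <- fsel[pk]
      # subharmonic candidates (j >= 2) must exceed the Hamming mainlobe
      # width (~4 resolution bins), else successive harmonics fall inside a
      # single broadened tooth and double-count it; the suprathreshold
      # peaks themselves are candidates at any frequency
      sub <- unique(round(as.vector(outer(fpk, 1 / (2:10))) / ps$df)) * ps$df
      sub <- sub[sub >= max(f_lo, 4 * ps$resolution_hz)]
      cands <- unique(c(fpk, sub))
      cands <- cands[cands >= f_lo & cands <= f_hi]
      score <- vapply(cands, function(f0) {
        harm <- f0 * seq_len(floor(f_hi / f0))
        sum(stats::approx(fsel, vals, xout = harm, rule = 2)$y) -
          length(harm) * floor_est
      }, numeric(1))
      best <- max(score)
      f0 <- max(cands[score >= 0.95 * best])
      res("welch", 1 / f0, max(vals[pk]), thr, TRUE)
    }
  }
  out
}

#' @export
print.mea_periodicity <- function(x, ...) {
  cat(sprintf("<mea_periodicity %s> %s (peak %.3g, threshold %.3g)\n",
              x$method,
              if (x$detected) sprintf("period %.3g s", x$period_s) else "no period detected",
              x$peak_value, x$detection_threshold))
  invisible(x)
}
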