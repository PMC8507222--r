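#' Relative narrow-band oscillatory power
#'
#' Welch power (default 2000 ms windows, 1000 ms overlap) of each
#' band-limited signal, integrated over that band's frequency support, then
#' normalized per channel so the six band fractions sum to 1. The inter-band
#' gaps are deliberately unassigned; normalization is over the six bands, not
#' total broadband power.
#'
#' @param band_signals named list of channels x samples matrices as returned
#'   by [sst_band_decompose()] (names must match `bands$name`); attribute
#'   `fs_hz` or the `fs_hz` argument supplies the rate.
#' @param bands band table as from [mea_bands()].
#' @param fs_hz sampling rate; default taken from `attr(band_signals, "fs_hz")`.
#' @param welch_window_ms,welch_overlap_ms Welch parameters (2000/1000 ms).
#' @return an `mea_band_power`: list with `abs_power` and `rel_power`
#'   (channels x bands matrices), `flag` (per-channel TRUE when total power
#'   is zero, in which case relative power is `NA`), and the Welch settings.
#' @export
relative_band_power <- function(band_signals, bands = mea_bands(),
                                fs_hz = attr(band_signals, "fs_hz"),
                                welch_window_ms = 2000, welch_overlap_ms = 1000) {
  if (is.null(fs_hz)) stop("sampling rate not supplied")
  stopifnot(all(bands$name %in% names(band_signals)))
  nch <- nrow(band_signals[[bands$name[1]]])
  absp <- matrix(0, nch, nrow(bands), dimnames = list(NULL, bands$name))
  for (b in seq_len(nrow(bands))) {
    sig <- band_signals[[bands$name[b]]]
    for (ch in seq_len(nch)) {
      ps <- welch_psd(sig[ch, ], fs_hz, window_s = welch_window_ms / 1000,
                      overlap_s = welch_overlap_ms / 1000, demean = FALSE)
      absp[ch, b] <- band_power_from_psd(ps, bands$low_hz[b], bands$high_hz[b])
    }
  }
  tot <- rowSums(absp)
  rel <- absp / ifelse(tot > 0, tot, NA_real_)
  structure(list(abs_power = absp, rel_power = rel, flag = tot == 0,
                 welch_window_ms = welch_window_ms,
                 welch_overlap_ms = welch_overlap_ms),
            class = "mea_band_power")
}

#' @export
print.mea_band_power <- function(x, ...) {
  cat("<mea_band_power> relative power (mean over channels):\n")
  print(round(colMeans(x$rel_power), 3))
  invisible(x)
}

#' Peak LFP amplitude per channel
#'
#' Maximum absolute voltage of each channel over the analysis window of an
#' LFP-rate recording. Organoid-level values are obtained by averaging over
#' active channels at the summary stage.
#'
#' @param rec an LFP-band [mea_recording()].
#' @return named numeric vector (volts), one entry per channel.
#' @export
lfp_peak_amplitude <- function(rec) {
  stopifnot(inherits(rec, "mea_recording"))
  stats::setNames(apply(abs(rec$data), 1, max), rec$channel_ids)
}

#' Band-power connectivity
#'
#' Per channel, the relative power of one narrow band is computed in every
#' `window_s` window (default 5 s windows over the full recording, i.e. 60
#' windows for 5 min); channels are then correlated (Pearson) on these
#' power time courses. Channels are connected when their coefficient strictly
#' exceeds the median + 1 SD of the off-diagonal coefficient distribution;
#' the coefficient is the edge weight.
#'
#' @param rec an LFP-rate [mea_recording()] (>= 2 channels, duration >=
#'   `2 * window_s`).
#' @param band band name (see [mea_bands()]).
#' @param window_s power-course window length in seconds (default 5).
#' @param bands band table.
#' @param welch_window_ms,welch_overlap_ms Welch settings within each window.
#' @return an `mea_graph` with basis `"band_power"` plus elements
#'   `power_series` (channels x windows relative-power matrix) and
#'   `corr_matrix`; windows with zero total power give `NA` series values and
#'   are excluded pairwise from the correlation.
#' @export
power_connectivity <- function(rec, band, window_s = 5, bands = mea_bands(),
                               welch_window_ms = 2000, welch_overlap_ms = 1000) {
  stopifnot(inherits(rec, "mea_recording"))
  if (nrow(rec$data) < 2) stop("need at least 2 channels")
  dur <- rec_duration(rec)
  if (dur < 2 * window_s)
    stop("recording (", dur, " s) shorter than 2 windows")
  band_row(band, bands) # validate
  nw <- floor(dur / window_s)
  wlen <- round(window_s * rec$fs_hz)
  nch <- nrow(rec$data)
  series <- matrix(NA_real_, nch, nw, dimnames = list(rec$channel_ids, NULL))
  for (w in seq_len(nw)) {
    idx <- ((w - 1L) * wlen + 1L):(w * wlen)
    for (ch in seq_len(nch)) {
      ps <- welch_psd(rec$data[ch, idx], rec$fs_hz,
                      window_s = welch_window_ms / 1000,
                      overlap_s = welch_overlap_ms / 1000)
      bp <- vapply(seq_len(nrow(bands)), function(b)
        band_power_from_psd(ps, bands$low_hz[b], bands$high_hz[b]), numeric(1))
      tot <- sum(bp)
      series[ch, w] <- if (tot > 0) bp[match(band, bands$name)] / tot else NA_real_
    }
  }
  r <- suppressWarnings(stats::cor(t(series), use = "pairwise.complete.obs"))
  diag(r) <- 1
  off <- r[upper.tri(r)]
  off <- off[!is.na(off)]
  thr <- stats::median(off) + stats::sd(off)
  g <- connectivity_graph(r, threshold = thr, basis = "band_power")
  g$power_series <- series
  g$corr_matrix <- r
  g$band <- band
  g
}
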