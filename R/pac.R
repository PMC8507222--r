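#' Instantaneous phase of a narrow-band signal
#'
#' Phase of the analytic signal (FFT half-spectrum method), in radians in
#' \[-pi, pi). For a pure sinusoid the unwrapped phase advances at 2*pi*f
#' per second.
#'
#' @param band_signal numeric vector, narrow-band.
#' @return numeric vector of phases; all-`NA` with attribute
#'   `flag = "zero_signal"` for an all-zero input.
#' @export
extract_phase <- function(band_signal) {
  if (all(band_signal == 0)) {
    out <- rep(NA_real_, length(band_signal))
    attr(out, "flag") <- "zero_signal"
    return(out)
  }
  ph <- Arg(analytic_signal(band_signal))
  ph[ph >= pi] <- -pi
  ph
}

#' Amplitude envelope of a narrow-band signal
#'
#' Modulus of the analytic signal. For `A * cos(2*pi*f*t)` the envelope is
#' approximately `A` away from the record edges.
#'
#' @param band_signal numeric vector, narrow-band.
#' @return non-negative numeric vector.
#' @export
extract_amplitude <- function(band_signal) {
  Mod(analytic_signal(band_signal))
}

#' Modulation index of phase-amplitude coupling
#'
#' The Kullback-Leibler modulation index: the mean amplitude in each of
#' `n_bins` phase bins is normalized to a distribution P, and
#' `MI = (log N - H(P)) / log N` where `H` is the Shannon entropy. `MI = 0`
#' iff the amplitude is uniformly distributed over phase; `MI = 1` when all
#' amplitude mass concentrates in a single bin. Phase bins that receive no
#' samples get zero mass (entropy is computed over non-empty bins) and the
#' result is flagged, since with a minute of data empty bins indicate
#' degenerate phase coverage.
#'
#' @param phase numeric vector of phases in radians.
#' @param amplitude numeric vector of non-negative envelopes, same length.
#' @param n_bins number of phase bins (default 18, i.e. 20 degrees).
#' @return an `mea_pac`: list with `mi`, `bin_amplitude_distribution`
#'   (probabilities summing to 1), `bin_centers` (radians), `n_bins`, `flag`
#'   (`NA`, `"zero_amplitude"` or `"empty_bins"`).
#' @export
modulation_index <- function(phase, amplitude, n_bins = 18) {
  if (length(phase) != length(amplitude))
    stop("`phase` and `amplitude` must have equal length")
  if (n_bins < 2) stop("`n_bins` must be >= 2")
  ok <- is.finite(phase) & is.finite(amplitude)
  phase <- phase[ok]; amplitude <- amplitude[ok]
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  pac <- function(mi, P, flag) structure(
    list(mi = mi, bin_amplitude_distribution = P, bin_centers = centers,
         n_bins = n_bins, flag = flag), class = "mea_pac")
  if (length(amplitude) == 0 || all(amplitude == 0))
    return(pac(NA_real_, rep(NA_real_, n_bins), "zero_amplitude"))
  bin <- findInterval(phase, edges, rightmost.closed = TRUE)
  bin[bin < 1L] <- 1L; bin[bin > n_bins] <- n_bins
  mean_amp <- vapply(seq_len(n_bins), function(b) {
    v <- amplitude[bin == b]
    if (length(v)) mean(v) else 0
  }, numeric(1))
  P <- mean_amp / sum(mean_amp)
  nz <- P > 0
  H <- -sum(P[nz] * log(P[nz]))
  pac((log(n_bins) - H) / log(n_bins), P,
      if (all(nz)) NA_character_ else "empty_bins")
}

#' @export
print.mea_pac <- function(x, ...) {
  cat(sprintf("<mea_pac> MI = %.4g (%d bins)%s\n", x$mi, x$n_bins,
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Phase-amplitude coupling panel over band pairs
#'
#' For every (phase band, amplitude band) pair — by default delta/theta
#' phases against low/upper gamma amplitudes — each channel of an LFP-rate
#' recording is zero-phase band-passed at the two bands, phase and envelope
#' are extracted from the analytic signals, and the modulation index is
#' computed. Metric names follow `mi_<phase>_<amp>`.
#'
#' @param rec an LFP-rate [mea_recording()].
#' @param phase_bands,amp_bands band names (defaults `c("delta", "theta")`
#'   and `c("low_gamma", "upper_gamma")`).
#' @param n_bins phase bins for the modulation index (default 18).
#' @param bands band table.
#' @return data.frame with columns `channel_id`, `metric`
#'   (`mi_<phase>_<amp>`), `mi`, `flag`; attribute `pac` holds the full
#'   `mea_pac` objects indexed `[[channel]][[metric]]`.
#' @export
pac_panel <- function(rec, phase_bands = c("delta", "theta"),
                      amp_bands = c("low_gamma", "upper_gamma"),
                      n_bins = 18, bands = mea_bands()) {
  stopifnot(inherits(rec, "mea_recording"))
  fs <- rec$fs_hz
  used <- unique(c(phase_bands, amp_bands))
  filt <- list()
  for (bn in used) {
    b <- band_row(bn, bands)
    if (b$high_hz >= fs / 2) stop("band above Nyquist: ", bn)
    filt[[bn]] <- filter_matrix(rec$data, fs, pass_lo = b$low_hz,
                                pass_hi = b$high_hz)
  }
  rows <- list(); full <- list()
  for (ch in seq_len(nrow(rec$data))) {
    cid <- rec$channel_ids[ch]
    full[[cid]] <- list()
    for (pb in phase_bands) {
      ph <- extract_phase(filt[[pb]][ch, ])
      for (ab in amp_bands) {
        am <- extract_amplitude(filt[[ab]][ch, ])
        metric <- paste0("mi_", pb, "_", ab)
        p <- modulation_index(ph, am, n_bins = n_bins)
        if (!is.null(attr(ph, "flag"))) p$flag <- attr(ph, "flag")
        full[[cid]][[metric]] <- p
        rows[[length(rows) + 1L]] <-
          data.frame(channel_id = cid, metric = metric, mi = p$mi,
                     flag = p$flag, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "pac") <- full
  out
}
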