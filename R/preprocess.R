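#' Savitzky-Golay smoothing of a raw recording
#'
#' Light polynomial smoothing applied to the raw signal before any band
#' splitting. A Savitzky-Golay filter fits a degree-`order` polynomial in a
#' sliding window, so any polynomial of degree <= `order` passes through
#' unchanged. The default is a second-order fit over 9 points; standard
#' Savitzky-Golay formulations require an odd window, so the nearest odd
#' window to the commonly quoted 8-point setting is used.
#'
#' @param rec an [mea_recording()].
#' @param order polynomial order (default 2).
#' @param window_points odd window length, must exceed `order` (default 9).
#' @return a smoothed `mea_recording` with identical shape and sampling rate.
#' @export
savgol_smooth <- function(rec, order = 2, window_points = 9) {
  stopifnot(inherits(rec, "mea_recording"))
  if (window_points %% 2 != 1) stop("`window_points` must be odd")
  if (window_points <= order) stop("`window_points` must exceed `order`")
  out <- rec$data
  for (i in seq_len(nrow(out)))
    out[i, ] <- signal::sgolayfilt(rec$data[i, ], p = order, n = window_points)
  mea_recording(out, rec$fs_hz, rec$channel_ids, rec$t0_s)
}

#' Spike-band (high-frequency) filtering
#'
#' Zero-phase band-pass isolating the multi-unit spike band (default
#' 300-2500 Hz) ahead of threshold spike detection. Zero phase matters here:
#' spike timing must not be shifted by the filter. The response is unity in
#' the pass band and rolls off to zero by 2/3 of the low edge and 1.5x the
#' high edge, giving > 40 dB attenuation at half the low edge and twice the
#' high edge.
#'
#' @param rec an [mea_recording()].
#' @param low_hz,high_hz pass-band edges in Hz; `high_hz` must be below the
#'   Nyquist frequency.
#' @return a filtered `mea_recording`.
#' @export
spike_band_filter <- function(rec, low_hz = 300, high_hz = 2500) {
  stopifnot(inherits(rec, "mea_recording"))
  if (low_hz <= 0 || high_hz <= low_hz)
    stop("invalid band: need 0 < low_hz < high_hz")
  if (high_hz >= rec$fs_hz / 2)
    stop("`high_hz` (", high_hz, ") must be below Nyquist (", rec$fs_hz / 2, ")")
  out <- filter_matrix(rec$data, rec$fs_hz, pass_lo = low_hz, pass_hi = high_hz)
  mea_recording(out, rec$fs_hz, rec$channel_ids, rec$t0_s)
}

#' Low-pass filtering and decimation to the LFP sampling rate
#'
#' Anti-alias low-pass followed by integer decimation, typically from
#' 25 000 Hz to the 1000 Hz local-field-potential rate. The default 400 Hz
#' cutoff sits comfortably below the target Nyquist frequency; the response
#' is zero above 1.2x the cutoff, so alias-band energy is suppressed far
#' beyond 40 dB.
#'
#' @param rec an [mea_recording()].
#' @param cutoff_hz anti-alias pass-band edge (default 400 Hz); must not
#'   exceed the target Nyquist frequency.
#' @param target_fs_hz output sampling rate; must divide `rec$fs_hz`.
#' @return an `mea_recording` sampled at `target_fs_hz`.
#' @export
lfp_downsample <- function(rec, cutoff_hz = 400, target_fs_hz = 1000) {
  stopifnot(inherits(rec, "mea_recording"))
  if (cutoff_hz > target_fs_hz / 2)
    stop("`cutoff_hz` (", cutoff_hz, ") exceeds target Nyquist (",
         target_fs_hz / 2, ")")
  if (rec$fs_hz == target_fs_hz) return(rec)
  factor <- rec$fs_hz / target_fs_hz
  if (abs(factor - round(factor)) > 1e-9)
    stop("`target_fs_hz` must divide the recording rate (",
         rec$fs_hz, " / ", target_fs_hz, " is not an integer)")
  factor <- as.integer(round(factor))
  stop_hi <- min(1.2 * cutoff_hz, 0.98 * target_fs_hz / 2)
  filt <- filter_matrix(rec$data, rec$fs_hz, pass_hi = cutoff_hz,
                        stop_hi = stop_hi)
  idx <- seq(1L, ncol(filt), by = factor)
  mea_recording(filt[, idx, drop = FALSE], target_fs_hz,
                rec$channel_ids, rec$t0_s)
}
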