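#' Multichannel MEA recording
#'
#' Container for an extracellular multielectrode-array recording: a
#' channels-by-samples voltage matrix plus sampling metadata. This is the root
#' object of the pipeline; every preprocessing stage takes and returns one.
#'
#' @param data numeric matrix, channels x samples, in volts. All values must
#'   be finite.
#' @param fs_hz sampling rate in samples per second (> 0).
#' @param channel_ids character vector of unique channel labels, one per row
#'   of `data`. Defaults to `"ch1"`, `"ch2"`, ...
#' @param t0_s recording start offset in seconds (default 0).
#'
#' @return An object of class `mea_recording`: a list with elements `data`,
#'   `fs_hz`, `channel_ids`, `t0_s`.
#' @examples
#' rec <- mea_recording(matrix(rnorm(2000), 2, 1000), fs_hz = 1000)
#' rec
#' rec_duration(rec)
#' @export
mea_recording <- function(data, fs_hz, channel_ids = NULL, t0_s = 0) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric channels x samples matrix")
  if (!all(is.finite(data)))
    stop("`data` contains non-finite values")
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0)
    stop("`fs_hz` must be a single positive number")
  if (is.null(channel_ids))
    channel_ids <- paste0("ch", seq_len(nrow(data)))
  channel_ids <- as.character(channel_ids)
  if (length(channel_ids) != nrow(data))
    stop("`channel_ids` length (", length(channel_ids),
         ") does not match number of channels (", nrow(data), ")")
  if (anyDuplicated(channel_ids))
    stop("`channel_ids` must be unique")
  structure(
    list(data = data, fs_hz = as.numeric(fs_hz),
         channel_ids = channel_ids, t0_s = as.numeric(t0_s)),
    class = "mea_recording"
  )
}

#' @rdname mea_recording
#' @param x,rec an `mea_recording`.
#' @export
rec_duration <- function(rec) ncol(rec$data) / rec$fs_hz

#' @rdname mea_recording
#' @export
n_channels <- function(rec) nrow(rec$data)

#' Sample times of a recording
#'
#' @param rec an `mea_recording`.
#' @return numeric vector of sample times in seconds (starting at `t0_s`).
#' @export
rec_times <- function(rec) {
  rec$t0_s + (seq_len(ncol(rec$data)) - 1L) / rec$fs_hz
}

#' @rdname mea_recording
#' @param ... ignored.
#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("<mea_recording> %d channels x %d samples @ %g Hz (%.2f s, t0 = %g s)\n",
              nrow(x$data), ncol(x$data), x$fs_hz,
              ncol(x$data) / x$fs_hz, x$t0_s))
  invisible(x)
}

#' @rdname mea_recording
#' @param channels channels to draw (ids or indices); default first 4.
#' @export
plot.mea_recording <- function(x, channels = NULL, ...) {
  if (is.null(channels)) channels <- seq_len(min(4L, nrow(x$data)))
  if (is.character(channels)) channels <- match(channels, x$channel_ids)
  tt <- rec_times(x)
  off <- 0
  step <- 2.5 * max(stats::sd(x$data[channels[1L], ]), .Machine$double.eps)
  graphics::plot(range(tt), c(-step, step * length(channels)), type = "n",
                 xlab = "time (s)", ylab = "", yaxt = "n", ...)
  for (ch in channels) {
    graphics::lines(tt, x$data[ch, ] + off)
    graphics::mtext(x$channel_ids[ch], side = 2, at = off, las = 1, cex = 0.7)
    off <- off + step
  }
  invisible(x)
}

# extract a contiguous time slice [start_s, start_s + dur_s); internal
rec_slice <- function(rec, start_s, dur_s) {
  i0 <- round((start_s - rec$t0_s) * rec$fs_hz) + 1L
  n <- round(dur_s * rec$fs_hz)
  if (i0 < 1L || i0 + n - 1L > ncol(rec$data))
    stop("slice outside recording span")
  mea_recording(rec$data[, i0:(i0 + n - 1L), drop = FALSE], rec$fs_hz,
                rec$channel_ids, t0_s = rec$t0_s + (i0 - 1L) / rec$fs_hz)
}
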