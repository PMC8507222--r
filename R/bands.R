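#' Canonical narrow-band frequency table
#'
#' The six EEG-style bands used throughout the oscillation and
#' phase-amplitude-coupling analyses: delta (0.5-4 Hz), theta (5-8), alpha
#' (9-13), beta (14-32), low gamma (33-80) and upper gamma (100-200 Hz).
#' Delta's lower edge is set to 0.5 Hz to exclude DC drift; the gaps between
#' bands (4-5, 8-9, 13-14, 32-33, 80-100 Hz) are deliberately unassigned, and
#' relative power is normalized over the six bands only.
#'
#' @return data.frame with columns `name`, `low_hz`, `high_hz`.
#' @examples
#' mea_bands()
#' @export
mea_bands <- function() {
  data.frame(
    name    = c("delta", "theta", "alpha", "beta", "low_gamma", "upper_gamma"),
    low_hz  = c(0.5, 5, 9, 14, 33, 100),
    high_hz = c(4, 8, 13, 32, 80, 200),
    stringsAsFactors = FALSE
  )
}

# band lookup with validation; `bands` is a mea_bands()-shaped data.frame
band_row <- function(name, bands = mea_bands()) {
  i <- match(name, bands$name)
  if (is.na(i)) stop("unknown band: ", name)
  bands[i, , drop = FALSE]
}

# representative carrier frequency (arithmetic band centre) used by the
# simulator so band-power ground truth is analytic
band_center_hz <- function(name, bands = mea_bands()) {
  b <- band_row(name, bands)
  (b$low_hz + b$high_hz) / 2
}

check_bands <- function(bands) {
  stopifnot(is.data.frame(bands),
            all(c("name", "low_hz", "high_hz") %in% names(bands)))
  if (any(bands$low_hz <= 0) || any(bands$high_hz <= bands$low_hz))
    stop("band edges must satisfy 0 < low_hz < high_hz")
  invisible(bands)
}
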