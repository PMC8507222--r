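# Internal DSP helpers: zero-phase frequency-domain filtering, the analytic
# signal, and a Welch PSD estimator.

# Reflection-pad a vector on both sides and round the total length up to a
# 2/3/5-smooth FFT size. Returns list(x, left, n).
pad_reflect <- function(x, min_pad) {
  n <- length(x)
  min_pad <- min(n - 1L, as.integer(min_pad))
  N <- stats::nextn(n + 2L * min_pad, c(2L, 3L, 5L))
  extra <- N - n
  left <- extra %/% 2L
  right <- extra - left
  if (left > n || right > n) { # degenerate: tile the reflection
    reps <- ceiling(max(left, right) / n)
    xr <- rev(x)
    tile <- rep(c(xr, x), reps)
    lp <- tile[(length(tile) - left + 1L):length(tile)]
    rp <- rep(c(xr, x), reps)[seq_len(right)]
    return(list(x = c(lp, x, rp), left = left, n = n))
  }
  lp <- if (left > 0L) x[left:1L] else numeric(0)
  rp <- if (right > 0L) x[n:(n - right + 1L)] else numeric(0)
  list(x = c(lp, x, rp), left = left, n = n)
}

# Raised-cosine frequency response on a grid of frequencies (Hz).
# Pass band [pass_lo, pass_hi]; response rolls off to exactly zero at
# stop_lo and stop_hi. Any of the four may be NULL (no edge on that side).
raised_cosine_response <- function(f, stop_lo, pass_lo, pass_hi, stop_hi) {
  H <- rep(1, length(f))
  if (!is.null(pass_lo)) {
    H[f < stop_lo] <- 0
    tr <- f >= stop_lo & f < pass_lo
    H[tr] <- 0.5 * (1 - cos(pi * (f[tr] - stop_lo) / (pass_lo - stop_lo)))
  }
  if (!is.null(pass_hi)) {
    H[f > stop_hi] <- 0
    tr <- f > pass_hi & f <= stop_hi
    H[tr] <- 0.5 * (1 + cos(pi * (f[tr] - pass_hi) / (stop_hi - pass_hi)))
  }
  H
}

# Zero-phase band-pass/low-pass/high-pass of a single channel via the FFT of
# the reflection-padded signal. Real response => exactly zero phase shift.
fft_zero_phase <- function(x, fs, pass_lo = NULL, pass_hi = NULL,
                           stop_lo = NULL, stop_hi = NULL) {
  if (!is.null(pass_lo) && is.null(stop_lo)) stop_lo <- pass_lo * 2 / 3
  if (!is.null(pass_hi) && is.null(stop_hi)) stop_hi <- min(pass_hi * 1.5, 0.999 * fs / 2)
  f_ref <- if (!is.null(pass_lo)) pass_lo else pass_hi
  pad <- pad_reflect(x, ceiling(3 * fs / max(f_ref, fs / length(x))))
  N <- length(pad$x)
  f <- c(seq(0, floor(N / 2)), seq(-ceiling(N / 2) + 1, -1)) * fs / N
  H <- raised_cosine_response(abs(f), stop_lo, pass_lo, pass_hi, stop_hi)
  y <- Re(stats::fft(stats::fft(pad$x) * H, inverse = TRUE)) / N
  y[(pad$left + 1L):(pad$left + pad$n)]
}

# Apply fft_zero_phase to every row of a channels x samples matrix.
filter_matrix <- function(m, fs, ...) {
  out <- m
  for (i in seq_len(nrow(m))) out[i, ] <- fft_zero_phase(m[i, ], fs, ...)
  out
}

# Analytic signal via half-spectrum doubling (Hilbert transform).
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Welch power spectral density: averaged modified periodograms with a Hamming
# window. Returns list(freq_hz, psd) with psd in units^2/Hz; sum(psd)*df
# approximates the signal variance. `nfft_pad` zero-pads each segment to
# interpolate the spectral grid (used by the periodicity estimator).
welch_psd <- function(x, fs, window_s = 2, overlap_s = 1, nfft_pad = 1,
                      demean = TRUE) {
  n <- length(x)
  seg <- min(n, max(8L, round(window_s * fs)))
  step <- max(1L, seg - round(overlap_s * fs))
  starts <- seq(1L, n - seg + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, seg - 1) / (seg - 1))
  U <- sum(w^2)
  nfft <- stats::nextn(seg * nfft_pad, c(2L, 3L, 5L))
  nf <- floor(nfft / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg_x <- x[s:(s + seg - 1L)]
    if (demean) seg_x <- seg_x - mean(seg_x)
    X <- stats::fft(c(seg_x * w, numeric(nfft - seg)))
    acc <- acc + Mod(X[seq_len(nf)])^2
  }
  psd <- acc / (length(starts) * fs * U)
  # one-sided: double everything except DC (and Nyquist when present)
  if (nfft %% 2 == 0) psd[2:(nf - 1L)] <- 2 * psd[2:(nf - 1L)]
  else psd[2:nf] <- 2 * psd[2:nf]
  list(freq_hz = (seq_len(nf) - 1L) * fs / nfft, psd = psd,
       n_segments = length(starts), df = fs / nfft,
       resolution_hz = fs / seg)
}

# Integrate a Welch PSD over [low, high] Hz (inclusive).
band_power_from_psd <- function(psd, low, high) {
  sel <- psd$freq_hz >= low & psd$freq_hz <= high
  sum(psd$psd[sel]) * psd$df
}

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
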