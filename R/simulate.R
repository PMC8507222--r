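#' Simulation configuration for synthetic MEA recordings
#'
#' Defines every knob of the synthetic recording generator: channel count,
#' duration and sampling rate, baseline noise, spike waveform amplitude,
#' tonic and burst firing rates, coordinated network events, additive
#' narrow-band oscillations and phase-amplitude coupling. Defaults are the
#' healthy-phenotype study conditions (8 channels, 60 s at 5000 Hz); see
#' [phenotype_preset()].
#'
#' @param n_channels number of electrodes.
#' @param duration_s recording length in seconds.
#' @param fs_hz sampling rate; must exceed twice the upper edge of every band
#'   with nonzero amplitude.
#' @param noise_sd baseline Gaussian noise SD in volts.
#' @param spike_amplitude peak magnitude of the injected spike waveform in
#'   volts (the waveform is negative-dominant per extracellular convention).
#' @param tonic_rate_hz homogeneous-Poisson firing rate per channel (Hz).
#' @param burst_rate_per_min Poisson rate of intrinsic bursts per channel.
#' @param spikes_per_burst,intra_burst_isi_ms burst structure: spike count
#'   and within-burst inter-spike interval (ms).
#' @param network_event_period_s period of coordinated network events in
#'   seconds, or `NA` for none. Events recruit a fixed random subset of
#'   `ceiling(network_participation * n_channels)` channels (drawn once per
#'   recording) with per-channel jitter up to 10 ms.
#' @param network_participation fraction of channels recruited per event.
#' @param band_amplitudes named vector (volts) of oscillation amplitudes per
#'   band name; oscillations are sinusoids at the band centre with slow
#'   random amplitude drift, added as a common signal.
#' @param pac_phase_band,pac_amp_band band names coupling slow phase to fast
#'   amplitude; with depth m the amplitude band's envelope is scaled by
#'   `(1 + m cos(phi)) / (1 + m)`, phi being the phase-band carrier phase.
#' @param pac_depth modulation depth in \[0, 1\].
#' @param osc_participation fraction of channels carrying the common
#'   oscillatory (LFP) component (default 1 = all).
#' @param seed integer RNG seed; identical configs give bit-identical output.
#' @return a validated `mea_sim_config` list.
#' @export
simulation_config <- function(n_channels = 8, duration_s = 60, fs_hz = 5000,
                              noise_sd = 5e-6, spike_amplitude = 5e-5,
                              tonic_rate_hz = 1, burst_rate_per_min = 3,
                              spikes_per_burst = 8, intra_burst_isi_ms = 10,
                              network_event_period_s = 5,
                              network_participation = 0.9,
                              band_amplitudes = c(delta = 1e-5, theta = 6e-6,
                                                  alpha = 5e-6, beta = 4e-6,
                                                  low_gamma = 4e-6,
                                                  upper_gamma = 6e-6),
                              pac_phase_band = "delta",
                              pac_amp_band = "upper_gamma",
                              pac_depth = 0.2,
                              osc_participation = 1,
                              seed = 1L) {
  cfg <- list(n_channels = as.integer(n_channels), duration_s = duration_s,
              fs_hz = fs_hz, noise_sd = noise_sd,
              spike_amplitude = spike_amplitude,
              tonic_rate_hz = tonic_rate_hz,
              burst_rate_per_min = burst_rate_per_min,
              spikes_per_burst = as.integer(spikes_per_burst),
              intra_burst_isi_ms = intra_burst_isi_ms,
              network_event_period_s = network_event_period_s,
              network_participation = network_participation,
              band_amplitudes = band_amplitudes,
              pac_phase_band = pac_phase_band, pac_amp_band = pac_amp_band,
              pac_depth = pac_depth, osc_participation = osc_participation,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "mea_sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  bands <- mea_bands()
  rates <- c(cfg$noise_sd, cfg$spike_amplitude, cfg$tonic_rate_hz,
             cfg$burst_rate_per_min, cfg$intra_burst_isi_ms)
  if (any(rates < 0)) stop("rates and amplitudes must be >= 0")
  if (cfg$n_channels < 1 || cfg$duration_s <= 0 || cfg$fs_hz <= 0)
    stop("invalid dimensions: need n_channels >= 1, duration_s > 0, fs_hz > 0")
  if (cfg$pac_depth < 0 || cfg$pac_depth > 1) stop("pac_depth must be in [0, 1]")
  if (cfg$network_participation < 0 || cfg$network_participation > 1)
    stop("network_participation must be in [0, 1]")
  if (cfg$osc_participation < 0 || cfg$osc_participation > 1)
    stop("osc_participation must be in [0, 1]")
  ba <- cfg$band_amplitudes
  if (length(ba)) {
    if (is.null(names(ba)) || !all(names(ba) %in% bands$name))
      stop("band_amplitudes names must be canonical band names")
    if (any(ba < 0)) stop("band amplitudes must be >= 0")
    active <- names(ba)[ba > 0]
    if (length(active)) {
      hi <- max(bands$high_hz[match(active, bands$name)])
      if (cfg$fs_hz <= 2 * hi)
        stop("fs_hz (", cfg$fs_hz, ") must exceed twice the upper band edge (",
             hi, " Hz)")
    }
  }
  if (cfg$pac_depth > 0) {
    for (bn in c(cfg$pac_phase_band, cfg$pac_amp_band)) band_row(bn, bands)
    if (is.na(ba[cfg$pac_phase_band]) || ba[cfg$pac_phase_band] <= 0 ||
        is.na(ba[cfg$pac_amp_band]) || ba[cfg$pac_amp_band] <= 0)
      stop("pac bands must have positive band_amplitudes when pac_depth > 0")
  }
  invisible(cfg)
}

# biphasic extracellular spike template: ~2 ms, negative-dominant,
# normalized so the negative peak has magnitude exactly 1
spike_template <- function(fs_hz) {
  tt <- seq(0, 0.002, by = 1 / fs_hz)
  w <- -exp(-0.5 * ((tt - 6e-4) / 3e-4)^2) + 0.25 * exp(-0.5 * ((tt - 1.4e-3) / 4.5e-4)^2)
  w <- w / abs(min(w))
  list(w = w, peak = which.min(w))
}

# slowly drifting positive envelope, mean ~1: coarse-grid Gaussian noise
# smoothed over tau_s and linearly interpolated to the sample grid
slow_drift <- function(n, fs_hz, depth = 0.3, tau_s = 2, fs_coarse = 4) {
  dur <- n / fs_hz
  m <- max(8L, ceiling(dur * fs_coarse) + 4L)
  z <- stats::rnorm(m)
  k <- ceiling(3 * tau_s * fs_coarse)
  kern <- stats::dnorm(seq(-k, k), sd = tau_s * fs_coarse)
  kern <- kern / sum(kern)
  zp <- c(rep(z[1], k), z, rep(z[m], k))
  sm <- as.numeric(stats::filter(zp, kern, sides = 2))[(k + 1):(k + m)]
  s <- stats::sd(sm)
  if (!is.finite(s) || s == 0) return(rep(1, n))
  sm <- sm / s
  tt <- (seq_len(n) - 1) / fs_hz
  env <- stats::approx(x = (seq_len(m) - 1) / fs_coarse, y = sm, xout = tt,
                       rule = 2)$y
  pmax(1 + depth * env, 0.05)
}

#' Simulate a synthetic MEA recording with ground truth
#'
#' Generates a multichannel extracellular recording from a
#' [simulation_config()]: per-channel Gaussian background noise, biphasic
#' spike waveforms injected at Poisson (tonic), clustered (intrinsic bursts)
#' and coordinated (periodic network events) times, additive narrow-band
#' oscillations at band-centre frequencies with slow amplitude drift, and
#' phase-amplitude coupling of the configured amplitude band's envelope to
#' the configured phase band. Identical configs (including seed) give
#' bit-identical output; the caller's RNG state is left untouched.
#'
#' @param config an `mea_sim_config`.
#' @return list with `recording` (an [mea_recording()]) and `truth`, an
#'   `mea_ground_truth` list: per-channel `spike_times` (sorted seconds) and
#'   `burst_intervals` (two-column matrices, merged/disjoint),
#'   `connected_pairs` (two-column character matrix of channel ids recruited
#'   into network events), `event_times` (seconds), `true_band_power`
#'   (fractions over the six bands from the realized components),
#'   `true_pac_depth`, and the `config`.
#' @export
simulate_recording <- function(config) {
  validate_sim_config(config)
  cfg <- config
  with_local_seed(cfg$seed, {
    fs <- cfg$fs_hz
    n <- round(cfg$duration_s * fs)
    nch <- cfg$n_channels
    tmpl <- spike_template(fs)
    L <- length(tmpl$w)
    t_lo <- tmpl$peak / fs
    t_hi <- cfg$duration_s - (L - tmpl$peak + 1) / fs
    bands <- mea_bands()
    tt <- (seq_len(n) - 1) / fs

    data <- matrix(stats::rnorm(nch * n, sd = cfg$noise_sd), nch, n)

    # ---- spike times -------------------------------------------------
    spike_times <- vector("list", nch)
    burst_spans <- vector("list", nch) # list of (first, last) per burst
    for (ch in seq_len(nch)) {
      st <- numeric(0)
      if (cfg$tonic_rate_hz > 0) {
        k <- stats::rpois(1, cfg$tonic_rate_hz * cfg$duration_s)
        st <- sort(stats::runif(k, t_lo, t_hi))
      }
      bs <- matrix(numeric(0), ncol = 2)
      if (cfg$burst_rate_per_min > 0 && cfg$spikes_per_burst > 0) {
        kb <- stats::rpois(1, cfg$burst_rate_per_min / 60 * cfg$duration_s)
        onsets <- sort(stats::runif(kb, t_lo, t_hi))
        for (o in onsets) {
          sp <- o + (seq_len(cfg$spikes_per_burst) - 1) * cfg$intra_burst_isi_ms / 1000
          sp <- sp[sp <= t_hi]
          if (length(sp)) {
            st <- c(st, sp)
            bs <- rbind(bs, c(min(sp), max(sp)))
          }
        }
      }
      spike_times[[ch]] <- st
      burst_spans[[ch]] <- bs
    }

    # ---- periodic network events ------------------------------------
    event_times <- numeric(0)
    subset_idx <- integer(0)
    if (is.finite(cfg$network_event_period_s) && cfg$network_event_period_s > 0 &&
        cfg$network_participation > 0) {
      period <- cfg$network_event_period_s
      event_times <- if (period / 2 <= cfg$duration_s - 0.2)
        seq(period / 2, cfg$duration_s - 0.2, by = period) else numeric(0)
      n_rec <- min(nch, ceiling(cfg$network_participation * nch))
      subset_idx <- sort(sample.int(nch, n_rec))
      for (ev in event_times) {
        for (ch in subset_idx) {
          o <- ev + stats::runif(1, 0, 0.010) # jitter <= 10 ms
          sp <- o + (seq_len(cfg$spikes_per_burst) - 1) * cfg$intra_burst_isi_ms / 1000
          sp <- sp[sp >= t_lo & sp <= t_hi]
          if (length(sp)) {
            spike_times[[ch]] <- c(spike_times[[ch]], sp)
            burst_spans[[ch]] <- rbind(burst_spans[[ch]], c(min(sp), max(sp)))
          }
        }
      }
    }

    # snap to the sample grid, sort, enforce a 2 ms refractory (absolute
    # neuronal refractory; also keeps injected events resolvable), inject
    for (ch in seq_len(nch)) {
      st <- sort(round(spike_times[[ch]] * fs) / fs)
      if (length(st) > 1) {
        keep <- logical(length(st)); last <- -Inf
        for (k in seq_along(st)) {
          if (st[k] - last >= 0.002) { keep[k] <- TRUE; last <- st[k] }
        }
        st <- st[keep]
      }
      spike_times[[ch]] <- st
      for (s in st) {
        pk <- round(s * fs) + 1L
        i0 <- pk - tmpl$peak + 1L
        data[ch, i0:(i0 + L - 1L)] <-
          data[ch, i0:(i0 + L - 1L)] + cfg$spike_amplitude * tmpl$w
      }
    }

    # merged ground-truth burst intervals
    burst_intervals <- lapply(seq_len(nch), function(ch) {
      bs <- burst_spans[[ch]]
      colnames(bs) <- c("start_s", "end_s")
      if (nrow(bs) <= 1) return(bs)
      bs <- bs[order(bs[, 1]), , drop = FALSE]
      out <- bs[1, , drop = FALSE]
      for (k in 2:nrow(bs)) {
        if (bs[k, 1] <= out[nrow(out), 2]) {
          out[nrow(out), 2] <- max(out[nrow(out), 2], bs[k, 2])
        } else out <- rbind(out, bs[k, , drop = FALSE])
      }
      out
    })

    # ---- oscillations and phase-amplitude coupling -------------------
    ba <- cfg$band_amplitudes[cfg$band_amplitudes > 0]
    osc_idx <- if (cfg$osc_participation >= 1) seq_len(nch)
               else sort(sample.int(nch, max(1L, ceiling(cfg$osc_participation * nch))))
    comp_power <- stats::setNames(numeric(nrow(bands)), bands$name)
    # draw carrier phase offsets in a fixed order so the PAC envelope can use
    # the realized phase of the phase band whatever the band ordering
    phi0 <- stats::setNames(stats::runif(length(ba), 0, 2 * pi), names(ba))
    osc_total <- numeric(n)
    for (bn in names(ba)) {
      f_c <- band_center_hz(bn, bands)
      env <- ba[[bn]] * slow_drift(n, fs)
      if (cfg$pac_depth > 0 && bn == cfg$pac_amp_band) {
        f_p <- band_center_hz(cfg$pac_phase_band, bands)
        ph_p <- 2 * pi * f_p * tt + phi0[[cfg$pac_phase_band]]
        env <- env * (1 + cfg$pac_depth * cos(ph_p)) / (1 + cfg$pac_depth)
      }
      comp <- env * cos(2 * pi * f_c * tt + phi0[[bn]])
      comp_power[bn] <- mean(comp^2)
      osc_total <- osc_total + comp
    }
    if (length(ba)) {
      for (ch in osc_idx) data[ch, ] <- data[ch, ] + osc_total
    }
    tbp <- if (sum(comp_power) > 0) comp_power / sum(comp_power)
           else comp_power * NA_real_

    ids <- paste0("ch", seq_len(nch))
    pairs <- if (length(subset_idx) >= 2) {
      cmb <- utils::combn(subset_idx, 2)
      cbind(ids[cmb[1, ]], ids[cmb[2, ]])
    } else matrix(character(0), ncol = 2)
    truth <- structure(
      list(spike_times = stats::setNames(spike_times, ids),
           burst_intervals = stats::setNames(burst_intervals, ids),
           connected_pairs = pairs,
           event_times = event_times,
           osc_channels = ids[osc_idx],
           true_band_power = tbp,
           true_pac_depth = cfg$pac_depth,
           config = cfg),
      class = "mea_ground_truth")
    list(recording = mea_recording(data, fs, ids), truth = truth)
  })
}

#' Phenotype presets for cohort simulation
#'
#' Two presets mirror the qualitative healthy-vs-disease contrast observed
#' on MEA: the mutant phenotype has a lower intrinsic burst rate, lower
#' network participation (weaker connectivity), stronger delta-band
#' oscillation, weaker low-gamma, and deeper delta-to-upper-gamma
#' phase-amplitude coupling. Magnitudes are the package's own choices of
#' realistic effect sizes, not measured values.
#'
#' @param preset `"healthy"` or `"mutant"`.
#' @param ... overrides passed to [simulation_config()].
#' @return an `mea_sim_config`.
#' @export
phenotype_preset <- function(preset = c("healthy", "mutant"), ...) {
  preset <- match.arg(preset)
  base <- list()
  if (preset == "mutant") {
    base <- list(tonic_rate_hz = 0.6, burst_rate_per_min = 1.5,
                 network_participation = 0.5,
                 band_amplitudes = c(delta = 2.5e-5, theta = 6e-6,
                                     alpha = 5e-6, beta = 4e-6,
                                     low_gamma = 2e-6, upper_gamma = 6e-6),
                 pac_depth = 0.6)
  }
  args <- utils::modifyList(base, list(...))
  do.call(simulation_config, args)
}

#' Simulate a cohort of organoid recordings
#'
#' Runs [simulate_recording()] `n_organoids` times under a phenotype preset;
#' organoid `i` uses seed `seed + i`, so cohorts are reproducible piecewise.
#'
#' @param preset `"healthy"` or `"mutant"`.
#' @param n_organoids number of recordings (>= 1).
#' @param seed master integer seed.
#' @param ... config overrides forwarded to [phenotype_preset()].
#' @return list of `list(recording, truth)` of length `n_organoids`.
#' @export
simulate_cohort <- function(preset, n_organoids, seed = 0L, ...) {
  if (n_organoids < 1) stop("`n_organoids` must be >= 1")
  lapply(seq_len(n_organoids), function(i)
    simulate_recording(phenotype_preset(preset, seed = seed + i, ...)))
}
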