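---
title: "Methods: spike, network, oscillation and PAC analysis of MEA recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike, network, oscillation and PAC analysis of MEA recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meawave)
```

# What the package computes

meawave analyses multielectrode-array (MEA) recordings of neuronal tissue —
cerebral organoids being the motivating preparation — and reduces each
recording to a panel of electrophysiological metrics used to phenotype
network function:

* **Firing**: per-electrode spike rate, burst rate, and the inter-spike
  interval coefficient of variation (ISI CV; 0 for clock-like firing, ~1 for
  Poisson firing).
* **Network communication**: an undirected functional-connectivity graph
  over electrodes from the Pearson correlation of binned spike counts
  (edges where r > 0.5), the percentage of connected electrodes, the mean
  edge weight, a burst-overlap graph, and the periodicity of "network
  events" (the fraction of active electrodes firing per 100 ms bin),
  estimated by both the autocorrelation and the Welch periodogram.
* **Oscillations**: relative power of the local field potential (LFP) in
  six canonical bands — delta (0.5–4 Hz), theta (5–8), alpha (9–13), beta
  (14–32), low gamma (33–80), upper gamma (100–200 Hz) — obtained from a
  synchrosqueezed continuous wavelet decomposition, plus the LFP peak
  amplitude and band-power connectivity between electrodes.
* **Cross-frequency coupling**: the Kullback–Leibler modulation index (MI)
  of delta/theta phase against low/upper-gamma amplitude.

Because public MEA recordings with known ground truth for all of these
quantities do not exist, the package ships a synthetic-recording generator
whose output carries exact ground truth (spike times, burst intervals,
connected pairs, band powers, coupling depth), so that every stage of the
pipeline is verifiable end to end.

# The processing chain

A raw recording (channels x samples, nominally 60 electrodes at 25 000 Hz)
passes through:

1. **Savitzky–Golay smoothing** (order 2). The window is 9 points at
   25 kHz; `analyze_recording()` scales the window with the sampling rate so
   that the smoothed time span (~0.36 ms) is rate-invariant — a fixed
   9-point window at 5 kHz would smooth five times harder and visibly
   attenuate sub-millisecond spike waveforms.
2. **Spike band-pass**, 300–2500 Hz (capped below Nyquist at lower rates),
   implemented as a zero-phase filter applied in the frequency domain with
   raised-cosine transitions (unity passband; zero response below 2/3 of
   the low edge and above 1.5x the high edge). Zero phase matters because
   spike times must not shift; the frequency-domain application is
   mathematically a zero-phase linear filter and meets 40 dB stopband /
   1 dB passband contracts by construction.
3. **Spike detection** at 4 baseline standard deviations, with the baseline
   mean and SD estimated per electrode from the first 30 s. Both polarities
   trigger on |x − mean|. Events are local extrema separated by a 2 ms dead
   time with amplitude priority (largest peak of a conflicting cluster
   wins). The dead time is 2 ms rather than ~1 ms for a structural reason:
   a band-passed spike is forced to zero mean, so a predominantly negative
   waveform acquires rebound lobes of roughly a third of its peak about
   1 ms on either side; with a 1 ms dead time those lobes double-count
   spikes and inflate burst rates by tens of percent. Electrodes with
   ≤ 12 spikes/min are inactive and are excluded from all organoid-level
   averages.
4. **Burst detection**: ≥ 4 spikes within any 100 ms window; overlapping
   qualifying windows (sharing a spike) merge into one burst spanning first
   to last member spike, so one long volley is never counted twice. The
   implementation is tested for exact equality against an exhaustive
   O(n²) window-enumeration oracle.
5. **Network metrics** on a single 60 s analysis window whose start is
   drawn uniformly (seeded): spike-count correlation in 50 ms bins, edges
   strictly above r = 0.5, and the network-event periodicity described
   below.
6. **LFP stage**: anti-alias low-pass (400 Hz) and integer decimation to
   1000 Hz, then the synchrosqueezed band decomposition, relative band
   power (Welch, 2000 ms windows, 1000 ms overlap, integrated over each
   band's support and normalised across the six bands), LFP peak
   amplitude, band-power connectivity (5 s windows; edges above the
   median + 1 SD of the coefficient distribution), and the PAC panel.

# Synchrosqueezed band decomposition

The decomposition uses an analytic Morlet wavelet (centre frequency 6 rad),
32 voices per octave over 0.5–450 Hz. For each scale the continuous wavelet
coefficient W(a, t) is computed by FFT; its instantaneous frequency is the
discrete phase derivative arg{W(a, t+1) W*(a, t)}·fs/2π; and the
coefficient is reassigned to the band whose support contains that
frequency. Band signals are reconstructed by the standard single-integral
inverse — summing reassigned coefficients over scales, scaled by
2·Δlog(a)/C where C is the Morlet admissibility constant computed by
quadrature. On a pure in-band tone the matching band recovers > 99 % of the
signal variance with < 2 % amplitude error, and the reconstruction agrees
with a zero-phase band-pass to within 10 % of band variance (both are
tested). Signals are reflection-padded (≥ 2 periods of the lowest analysed
frequency) to suppress edge effects, and the per-scale spectral window is
truncated where the Gaussian falls below e⁻⁶⁰.

Relative power is normalised over the six bands only; the inter-band gaps
(4–5, 8–9, 13–14, 32–33, 80–100 Hz) are deliberately unassigned, which
makes the sum-to-one invariant exact and testable. Delta's lower edge is
0.5 Hz to exclude DC drift.

# Periodicity detection

The network-event series (fraction of active electrodes firing per 100 ms
bin) is tested for periodicity over lags 0.5–30 s (0.033–2 Hz):

* **Autocorrelation route**: the normalized autocorrelation; a period is
  the smallest-lag local peak above the detection threshold.
* **Welch route**: averaged periodograms (segments of one third of the
  series, 50 % overlap, 16x zero-padding for grid resolution).

The detection threshold combines the mean + 1 SD of the values over the
search range with a white-noise significance guard at a family-wise 1 %
level (a max-calibrated Gaussian bound on autocorrelation values; a
chi-square bound on the segment-averaged periodogram, with the noise floor
estimated from the lower quartile so the signal's own peaks do not inflate
it). The guard exists because the mean + 1 SD rule alone fires on pure
noise almost surely — the largest of ~300 fluctuating values always exceeds
mean + 1 SD — which would make "no periodicity" an impossible outcome.

A periodic train of brief network events is a harmonic comb in the
spectrum, and the fundamental tooth can be weaker than its harmonics at
minute-scale record lengths. The Welch period is therefore chosen by a
harmonic-sum score: candidate fundamentals (each suprathreshold peak and
its subharmonics, restricted to spacings wider than the Hamming mainlobe)
are scored by the floor-corrected power summed over their harmonics inside
the search band, and near-ties resolve to the highest candidate frequency.
This integrates the comb coherently, exactly as the autocorrelation does,
and reduces to "the highest peak" for a single-peak spectrum.

# Phase–amplitude coupling

Phase and amplitude are extracted from zero-phase FIR-equivalent
band-passed signals via the analytic signal (FFT half-spectrum method),
not from the synchrosqueezed rows — the standard construction for the KL
modulation index. The MI bins phase into 18 bins of 20°, normalises the
mean amplitude per bin to a distribution P, and reports
(log N − H(P))/log N. It is exactly 0 for phase-uniform amplitude, exactly
1 when all amplitude mass concentrates in one bin, invariant to amplitude
scaling and global phase rotation, and monotone in the generator's coupling
depth; it is verified against an independent histogram-binning oracle to
1e-9. Empty phase bins receive zero mass and flag the result, since with a
minute of data at 1000 Hz empty bins indicate degenerate phase coverage.
Note that the MI itself scales like 1/log N in the bin count for smooth
modulation (the underlying KL divergence is the bin-stable quantity); all
reported MIs use 18 bins.

# The synthetic generator

`simulate_recording()` builds each channel as the sum of:

* Gaussian background noise (SD 5 µV);
* biphasic extracellular spike waveforms (~2 ms, negative-dominant with a
  shallow positive rebound, peak magnitude exactly `spike_amplitude`,
  default 50 µV = 10x the noise SD) injected at sample-aligned times from
  three processes: homogeneous-Poisson tonic firing, Poisson-seeded
  intrinsic bursts (`spikes_per_burst` spikes at `intra_burst_isi_ms`
  spacing), and periodic network events that recruit a fixed random subset
  of ⌈participation·n⌉ channels with ≤ 10 ms jitter. A 2 ms per-channel
  refractory (the absolute neuronal refractory) is enforced, which also
  keeps injected events resolvable by any detector with a matching dead
  time;
* narrow-band oscillations: sinusoids at band-centre frequencies with a
  slow (~2 s correlation time, ±30 %) random amplitude drift, added as a
  common LFP component to all channels (or a configured fraction, for
  band-power-connectivity ground truth);
* phase–amplitude coupling: the amplitude-band envelope is scaled by
  (1 + m·cos φ)/(1 + m) with φ the realized phase of the phase-band
  carrier and m the configured depth.

Ground truth records spike times, merged burst intervals, the recruited
(connected) channel subset, event times, realized band-power fractions and
the coupling depth. Identical configurations are bit-reproducible and the
caller's RNG state is untouched.

**Phenotype presets.** The study contrast is healthy vs mutant at reduced
desk scale (8 channels, 60 s, 5 kHz spike stage / 1 kHz LFP stage). The
healthy preset fires tonically at 1 Hz with 3 intrinsic bursts/min/channel
and 5 s-periodic network events recruiting 90 % of channels; delta
amplitude 10 µV and coupling depth 0.2. The mutant preset lowers tonic
rate (0.6 Hz), intrinsic bursts (1.5/min) and participation (50 %), raises
delta to 25 µV, lowers low gamma (2 µV), and deepens delta→upper-gamma
coupling to 0.6. These magnitudes are this package's choices of plausible
effect sizes — the motivating observations are figure-level, without
printed effect sizes — picked so that each contrast is comfortably larger
than sampling variability at n = 10 per group, and so that co-recruited
channels genuinely satisfy the r > 0.5 edge rule (network events must
dominate binned-count variance relative to solo bursts; a generator whose
"connected" channels do not exceed the edge threshold would contradict its
own ground truth). Intra-burst structure (8 spikes at 10 ms) matches the
4-in-100-ms burst rule with ample margin.

**What the generator does not emulate**: electrode geometry and volume
conduction, spike waveform diversity across units, non-stationary rates,
1/f background spectra, line noise, and movement or electrode artifacts.
Passing recovery tests on this generator therefore demonstrates the
correctness of the analysis chain under controlled conditions, not
robustness to every pathology of real recordings.

# Numerical choices and degenerate inputs

* The quoted 8-point Savitzky–Golay window is even; standard formulations
  need an odd window, so the default is the nearest valid odd window
  (9 points at 25 kHz).
* "High-pass 300–2500 Hz" names a band and is implemented as a band-pass.
* Constant channels (zero baseline SD) return an empty, flagged spike
  train; zero-variance series flag the periodicity result; all-zero
  signals flag band power, phase and MI as undefined — never silent zeros.
* The ISI CV is undefined (NA) below 3 spikes.
* Active-electrode classification is strict: exactly 12 spikes/min is
  inactive.
* Graph edges require correlation strictly above threshold, matching the
  "above 0.5" rule; the boundary is tested on a 0.01 grid.
* Storage defaults to float64 so HDF5 round trips are bit-exact; float32
  is available for bulk raw data.
* Problem sizes in the test-suite and acceptance runs are the reduced
  study conditions above (plus 300 s spike-stage recordings for
  periodicity, matching the ~5 min recording protocol); they were chosen
  so the full verification runs on a single CPU in well under an hour.

# Known limitations

* The periodicity significance guard and the harmonic-sum fundamental are
  this package's constructions; other toolboxes implementing only the
  mean + 1 SD peak rule will report periods for unstructured series where
  meawave reports none.
* Band-power connectivity interprets the "median + 1 SD" edge rule
  literally; no additional confidence-interval machinery is applied.
* Group comparison (`group_compare()`) is a thin convenience — a
  Kruskal–Wallis omnibus plus reference-vs-group rank-sum tests with Holm
  correction. Rank-based many-to-one testing with Dunnett-style correction
  has no exact standard analogue; Holm is conservative and family-wise
  valid.
* No spike sorting: a channel is multi-unit population activity.
* Only correlation-based (undirected) connectivity; no causal measures.
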