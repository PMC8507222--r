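test_that("identical configs give bit-identical recordings and truth", {
  cfg <- simulation_config(n_channels = 3, duration_s = 35, seed = 7)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$truth$spike_times, b$truth$spike_times)
  expect_identical(a$truth$connected_pairs, b$truth$connected_pairs)
})

test_that("simulation leaves the caller's RNG state untouched", {
  set.seed(42)
  before <- .Random.seed
  invisible(simulate_recording(simulation_config(n_channels = 1,
                                                 duration_s = 2, seed = 3)))
  expect_identical(.Random.seed, before)
})

test_that("a config with no sources yields pure Gaussian noise", {
  cfg <- simulation_config(n_channels = 2, duration_s = 5, tonic_rate_hz = 0,
                           burst_rate_per_min = 0, network_event_period_s = NA,
                           band_amplitudes = c(delta = 0), pac_depth = 0,
                           seed = 1)
  s <- simulate_recording(cfg)
  expect_true(all(lengths(s$truth$spike_times) == 0))
  expect_equal(sd(s$recording$data), cfg$noise_sd, tolerance = 0.05)
  expect_lt(abs(mean(s$recording$data)), 3 * cfg$noise_sd / sqrt(length(s$recording$data)))
})

test_that("tonic spike counts follow the configured Poisson rate", {
  # mean = rate * duration * channels = 2 * 300 * 8 = 4800; the 2 ms
  # refractory thins at most rate * refr ~ 0.4% of events
  cfg <- simulation_config(n_channels = 8, duration_s = 300, fs_hz = 5000,
                           tonic_rate_hz = 2, burst_rate_per_min = 0,
                           network_event_period_s = NA,
                           band_amplitudes = c(delta = 0), pac_depth = 0,
                           seed = 11)
  s <- simulate_recording(cfg)
  total <- sum(lengths(s$truth$spike_times))
  expect_lt(abs(total - 4800), 4 * sqrt(4800) + 0.004 * 4800)
})

test_that("ground truth invariants hold: sorted times, disjoint intervals", {
  s <- simulate_recording(simulation_config(seed = 5))
  for (st in s$truth$spike_times)
    expect_true(all(diff(st) > 0))
  for (bi in s$truth$burst_intervals) {
    if (nrow(bi) > 1) expect_true(all(bi[-1, 1] > bi[-nrow(bi), 2]))
    expect_true(all(bi[, 2] >= bi[, 1]))
  }
})

test_that("injected waveform peaks equal spike_amplitude on the noiseless component", {
  cfg <- simulation_config(n_channels = 2, duration_s = 30, noise_sd = 0,
                           band_amplitudes = c(delta = 0), pac_depth = 0,
                           tonic_rate_hz = 1, burst_rate_per_min = 2,
                           network_event_period_s = 5, seed = 9)
  s <- simulate_recording(cfg)
  amp <- cfg$spike_amplitude
  for (ch in 1:2) {
    x <- s$recording$data[ch, ]
    tt <- s$truth$spike_times[[ch]]
    # template-matched recovery: local minima below half amplitude
    idx <- which(x < -0.5 * amp)
    idx <- idx[x[idx] <= x[pmax(idx - 1, 1)] & x[idx] <= x[pmin(idx + 1, length(x))]]
    det <- (idx - 1) / cfg$fs_hz
    expect_gte(match_fraction(tt, det, tol_s = 1 / cfg$fs_hz + 1e-9), 0.99)
    # isolated spikes carry exactly the configured peak magnitude
    iso <- tt[vapply(tt, function(t0) sum(abs(tt - t0) < 0.004) == 1, logical(1))]
    pk <- vapply(iso, function(t0) min(x[round(t0 * cfg$fs_hz) + 1 + (-2:2)]),
                 numeric(1))
    expect_equal(unname(pk), rep(-amp, length(iso)), tolerance = 1e-12)
  }
})

test_that("a single nonzero band concentrates spectral power inside its edges", {
  bands <- mea_bands()
  for (bn in c("delta", "beta", "upper_gamma")) {
    ba <- c(1e-5); names(ba) <- bn
    cfg <- simulation_config(n_channels = 1, duration_s = 30, fs_hz = 1000,
                             noise_sd = 0, tonic_rate_hz = 0,
                             burst_rate_per_min = 0,
                             network_event_period_s = NA,
                             band_amplitudes = ba, pac_depth = 0, seed = 2)
    s <- simulate_recording(cfg)
    ps <- meawave:::welch_psd(s$recording$data[1, ], 1000)
    b <- bands[bands$name == bn, ]
    inband <- meawave:::band_power_from_psd(ps, b$low_hz, b$high_hz)
    total <- sum(ps$psd) * ps$df
    expect_gt(inband / total, 0.90)
  }
})

test_that("analytic modulation index of the noiseless PAC component is monotone in depth", {
  mis <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(m) {
    cfg <- simulation_config(n_channels = 1, duration_s = 60, fs_hz = 1000,
                             noise_sd = 0, tonic_rate_hz = 0,
                             burst_rate_per_min = 0, network_event_period_s = NA,
                             band_amplitudes = c(delta = 1e-5, upper_gamma = 5e-6),
                             pac_depth = m, seed = 4)
    s <- simulate_recording(cfg)
    pp <- pac_panel(s$recording, phase_bands = "delta", amp_bands = "upper_gamma")
    pp$mi[1]
  }, numeric(1))
  expect_true(all(diff(mis) > 0))
  expect_lt(mis[1], 1e-3)
})

test_that("phenotype presets order as the disease contrast requires", {
  h <- phenotype_preset("healthy")
  m <- phenotype_preset("mutant")
  expect_lt(m$burst_rate_per_min, h$burst_rate_per_min)
  expect_lt(m$network_participation, h$network_participation)
  expect_gt(m$band_amplitudes[["delta"]], h$band_amplitudes[["delta"]])
  expect_gt(m$pac_depth, h$pac_depth)
  expect_error(phenotype_preset("wildtype"))
})

test_that("cohorts are reproducible and organoid-distinct", {
  a <- simulate_cohort("healthy", 3, seed = 5, duration_s = 5, n_channels = 2)
  b <- simulate_cohort("healthy", 3, seed = 5, duration_s = 5, n_channels = 2)
  expect_identical(a[[2]]$recording$data, b[[2]]$recording$data)
  expect_false(identical(a[[1]]$recording$data, a[[2]]$recording$data))
  expect_error(simulate_cohort("healthy", 0))
})

test_that("invalid configs are rejected", {
  expect_error(simulation_config(pac_depth = 1.5), "pac_depth")
  expect_error(simulation_config(network_participation = -0.1))
  expect_error(simulation_config(tonic_rate_hz = -1))
  expect_error(simulation_config(fs_hz = 300), "twice the upper band edge")
  expect_error(simulation_config(band_amplitudes = c(sigma = 1e-6)))
  # PAC requires its bands to be present
  expect_error(simulation_config(band_amplitudes = c(theta = 1e-6),
                                 pac_depth = 0.5))
})
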