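mk_train <- function(times, id = "ch1") {
  structure(list(channel_id = id, times_s = times, degenerate = FALSE),
            class = "mea_spike_train")
}

test_that("constant channels yield an empty flagged train, not an error", {
  rec <- mea_recording(matrix(0, 2, 35 * 1000), 1000)
  rec$data[2, ] <- rnorm(35000)
  trains <- detect_spikes(rec, baseline_window_s = 30)
  expect_identical(length(trains[[1]]$times_s), 0L)
  expect_true(trains[[1]]$degenerate)
  expect_false(trains[[2]]$degenerate)
  expect_error(detect_spikes(mea_recording(matrix(0, 1, 100), 1000)),
               "shorter than baseline")
})

test_that("the realized threshold is baseline mean + multiplier * SD", {
  set.seed(8)
  rec <- mea_recording(matrix(rnorm(40000, mean = 2, sd = 0.5), 1), 1000)
  tr <- detect_spikes(rec, sd_multiplier = 4, baseline_window_s = 30)[[1]]
  nb <- 30000
  expect_equal(tr$baseline_mean_v, mean(rec$data[1, 1:nb]))
  expect_equal(tr$threshold_v,
               mean(rec$data[1, 1:nb]) + 4 * sd(rec$data[1, 1:nb]))
})

test_that("spike count is non-increasing in the SD multiplier", {
  set.seed(4)
  rec <- mea_recording(matrix(rnorm(60000), 1), 2000)
  counts <- vapply(c(2, 3, 4, 5, 6), function(k)
    length(detect_spikes(rec, sd_multiplier = k)[[1]]$times_s), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("noise-only false-event rate matches the analytic local-extremum oracle", {
  # P(sample is a local max of |x| above k*sd) for iid Gaussian noise:
  # 2 * integral_k^inf phi(u) Phi(u)^2 du (both polarities, iid neighbours)
  k <- 4
  p <- 2 * stats::integrate(function(u) dnorm(u) * pnorm(u)^2, k, Inf)$value
  n_per <- 120000
  set.seed(31)
  counts <- vapply(1:10, function(i) {
    rec <- mea_recording(matrix(rnorm(n_per), 1), 2000)
    length(detect_spikes(rec, sd_multiplier = k, baseline_window_s = 30)[[1]]$times_s)
  }, numeric(1))
  expected <- 10 * n_per * p
  expect_lt(abs(sum(counts) - expected), 3 * sqrt(expected) + 0.1 * expected)
})

test_that("the activity boundary is strictly more than 12 spikes per minute", {
  expect_false(classify_active(mk_train(seq_len(12) / 13 * 60), 60))
  expect_true(classify_active(mk_train(seq_len(13) / 14 * 60), 60))
  expect_false(classify_active(mk_train(numeric(0)), 60))
  # rate is per minute: 7 spikes in 30 s is 14/min
  expect_true(classify_active(mk_train(seq_len(7) * 4), 30))
  expect_error(classify_active(mk_train(1), 0))
})

test_that("burst rule: at least 4 spikes within 100 ms, merged windows", {
  b <- detect_bursts(mk_train(c(0, 0.030, 0.060, 0.090)))
  expect_identical(nrow(b$intervals), 1L)
  expect_equal(unname(b$intervals[1, ]), c(0, 0.090))
  expect_identical(b$spike_counts, 4L)
  expect_identical(nrow(detect_bursts(mk_train(c(0, 0.040, 0.080)))$intervals), 0L)
  # a prolonged volley is one burst, not several
  long <- mk_train(seq(0, 0.5, by = 0.02))
  bl <- detect_bursts(long)
  expect_identical(nrow(bl$intervals), 1L)
  expect_identical(bl$spike_counts, length(long$times_s))
})

test_that("burst detection equals the exhaustive window-enumeration oracle", {
  set.seed(21)
  for (rep in 1:300) {
    n <- sample(5:80, 1)
    times <- sort(runif(n, 0, 10))
    got <- detect_bursts(mk_train(times))
    want <- oracle_bursts(times)
    expect_identical(nrow(got$intervals), nrow(want$intervals))
    expect_equal(unname(got$intervals), unname(want$intervals))
    expect_identical(as.integer(got$spike_counts), as.integer(want$counts))
  }
})

test_that("burst count is monotone in min_spikes and window_ms", {
  set.seed(13)
  times <- sort(runif(300, 0, 20))
  tr <- mk_train(times)
  by_min <- vapply(3:6, function(m)
    nrow(detect_bursts(tr, min_spikes = m)$intervals), numeric(1))
  expect_true(all(diff(by_min) <= 0))
  by_win <- vapply(c(50, 100, 200, 400), function(w)
    nrow(detect_bursts(tr, window_ms = w)$intervals), numeric(1))
  # wider windows can merge bursts, but total burst *spikes* never shrink
  spk <- vapply(c(50, 100, 200, 400), function(w)
    sum(detect_bursts(tr, window_ms = w)$spike_counts), numeric(1))
  expect_true(all(diff(spk) >= 0))
})

test_that("channel statistics: rates, ISI CV, degenerate cases", {
  tr <- mk_train(seq(0.5, 60, by = 0.5))   # 120 spikes in 60 s, constant ISI
  st <- channel_stats(tr, detect_bursts(tr), 60)
  expect_equal(st$spike_rate_hz, 2)
  expect_equal(st$isi_cv, 0)
  expect_true(st$active)
  expect_true(is.na(channel_stats(mk_train(c(1, 2)), NULL, 60)$isi_cv))
  expect_error(channel_stats(tr, NULL, 0))
  # Poisson train: CV converges to 1
  set.seed(6)
  pt <- mk_train(cumsum(rexp(5000, rate = 2)))
  cv <- channel_stats(pt, NULL, max(pt$times_s))$isi_cv
  expect_lt(abs(cv - 1), 3 * sqrt(2 / 5000) * 2)
})

test_that("detected burst spikes are detected spikes inside the recording span", {
  s <- simulate_recording(simulation_config(seed = 17, duration_s = 40))
  filt <- spike_band_filter(savgol_smooth(s$recording, window_points = 5),
                            300, 2000)
  trains <- detect_spikes(filt)
  for (tr in trains) {
    b <- detect_bursts(tr)
    if (nrow(b$intervals) == 0) next
    expect_true(all(b$intervals[, 1] %in% tr$times_s))
    expect_true(all(b$intervals[, 2] %in% tr$times_s))
    expect_true(all(b$intervals >= 0 & b$intervals <= rec_duration(filt)))
  }
})

test_that("burst rate recovered within 15% of ground truth across seeds", {
  for (sd in 101:105) {
    s <- simulate_recording(simulation_config(seed = sd))
    filt <- spike_band_filter(savgol_smooth(s$recording, window_points = 5),
                              300, 2000)
    est <- sum(vapply(detect_spikes(filt), function(tr)
      nrow(detect_bursts(tr)$intervals), numeric(1)))
    tru <- sum(vapply(s$truth$burst_intervals, nrow, integer(1)))
    expect_lt(abs(est - tru) / tru, 0.15)
  }
})
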