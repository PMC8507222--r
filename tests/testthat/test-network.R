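mk_train <- function(times, id = "ch1") {
  structure(list(channel_id = id, times_s = times, degenerate = FALSE),
            class = "mea_spike_train")
}

test_that("analysis window selection is reproducible, uniform, and exact-length", {
  rec <- mea_recording(matrix(rnorm(2 * 300 * 100), 2), 100)
  w1 <- select_analysis_window(rec, 60, seed = 5)
  w2 <- select_analysis_window(rec, 60, seed = 5)
  expect_identical(w1$data, w2$data)
  expect_equal(rec_duration(w1), 60)
  # exactly window-length recording is returned whole
  rec60 <- mea_recording(matrix(rnorm(6000), 1), 100)
  expect_identical(select_analysis_window(rec60, 60)$data, rec60$data)
  expect_error(select_analysis_window(rec60, 120), "shorter")
  starts <- vapply(1:2000, function(i)
    select_analysis_window(rec, 60, seed = i)$t0_s, numeric(1))
  ks <- suppressWarnings(stats::ks.test(starts, "punif", 0, 240))
  expect_gt(ks$p.value, 0.001)
})

test_that("spike correlation: perfect copies give 1, independent trains stay low", {
  t1 <- sort(runif(200, 0, 60))
  cm <- spike_correlation_matrix(list(mk_train(t1, "a"), mk_train(t1, "b")),
                                 t_start_s = 0, duration_s = 60)
  expect_equal(cm["a", "b"], 1)
  set.seed(12)
  rs <- replicate(200, {
    a <- mk_train(cumsum(rexp(150, 3)), "a")
    b <- mk_train(cumsum(rexp(150, 3)), "b")
    spike_correlation_matrix(list(a, b), t_start_s = 0, duration_s = 50)["a", "b"]
  })
  expect_gte(mean(abs(rs) < 0.5), 0.99)
  expect_error(spike_correlation_matrix(list(mk_train(1:3)), t_start_s = 0,
                                        duration_s = 10))
})

test_that("silent channels give flagged NA correlations, excluded from edges", {
  cm <- spike_correlation_matrix(list(mk_train(sort(runif(100, 0, 30)), "a"),
                                      mk_train(numeric(0), "b")),
                                 t_start_s = 0, duration_s = 30)
  expect_true(is.na(cm["a", "b"]))
  g <- connectivity_graph(cm)
  expect_identical(nrow(g$edges), 0L)
})

test_that("edges require correlation strictly above the threshold", {
  m <- matrix(c(1, 0.4, 0.4, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  g <- connectivity_graph(m)
  expect_identical(nrow(g$edges), 0L)
  expect_equal(g$percent_connected, 0)
  m[1, 2] <- m[2, 1] <- 0.51
  g2 <- connectivity_graph(m)
  expect_identical(nrow(g2$edges), 1L)
  expect_equal(g2$percent_connected, 100)
  expect_equal(g2$mean_weight, 0.51)
  expect_error(connectivity_graph(matrix(c(1, 0.2, 0.8, 1), 2)), "symmetric")
})

test_that("raising the threshold never adds edges; relabeling leaves percent unchanged", {
  set.seed(7)
  n <- 6
  m <- crossprod(matrix(rnorm(n * n), n))
  m <- stats::cov2cor(m)
  dimnames(m) <- list(paste0("ch", 1:n), paste0("ch", 1:n))
  edge_counts <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(th)
    nrow(connectivity_graph(m, threshold = th)$edges), numeric(1))
  expect_true(all(diff(edge_counts) <= 0))
  perm <- sample(n)
  m2 <- m[perm, perm]
  expect_equal(connectivity_graph(m2, 0.4)$percent_connected,
               connectivity_graph(m, 0.4)$percent_connected)
})

test_that("overlapping-burst connectivity matches the interval-intersection oracle", {
  mk_bursts <- function(iv, id) structure(
    list(channel_id = id, intervals = iv, spike_counts = rep(4L, nrow(iv))),
    class = "mea_burst_set")
  ivA <- cbind(c(0, 1, 2), c(0.2, 1.2, 2.2))
  same <- overlapping_burst_connectivity(list(mk_bursts(ivA, "a"),
                                              mk_bursts(ivA, "b")))
  expect_identical(nrow(same$edges), 1L)
  expect_equal(same$edges$weight, 1)
  ivB <- cbind(c(5, 6), c(5.1, 6.1))
  none <- overlapping_burst_connectivity(list(mk_bursts(ivA, "a"),
                                              mk_bursts(ivB, "b")))
  expect_identical(nrow(none$edges), 0L)
  # random placements vs brute-force fractions
  set.seed(9)
  for (rep in 1:50) {
    na <- sample(1:12, 1); nb <- sample(1:12, 1)
    sa <- sort(runif(na, 0, 10)); sb <- sort(runif(nb, 0, 10))
    iva <- cbind(sa, sa + runif(na, 0.05, 0.4))
    ivb <- cbind(sb, sb + runif(nb, 0.05, 0.4))
    fa <- mean(vapply(seq_len(na), function(k)
      any(iva[k, 1] <= ivb[, 2] & ivb[, 1] <= iva[k, 2]), logical(1)))
    fb <- mean(vapply(seq_len(nb), function(k)
      any(ivb[k, 1] <= iva[, 2] & iva[, 1] <= ivb[k, 2]), logical(1)))
    g <- overlapping_burst_connectivity(list(mk_bursts(iva, "a"),
                                             mk_bursts(ivb, "b")),
                                        min_overlap_fraction = 0.25)
    expect_identical(nrow(g$edges) == 1L, max(fa, fb) > 0.25)
  }
})

test_that("network spiking percentage is a fraction with the right length", {
  t1 <- mk_train(seq(0.05, 9.95, by = 0.1), "a")   # fires every bin
  t2 <- mk_train(numeric(0), "b")
  nsp <- network_spiking_percentage(list(t1, t2), t_start_s = 0, duration_s = 10)
  expect_identical(length(nsp$series), 100L)
  expect_true(all(nsp$series == 0.5))
  all_fire <- network_spiking_percentage(list(t1), t_start_s = 0, duration_s = 10)
  expect_true(all(all_fire$series == 1))
  silent <- network_spiking_percentage(list(t2), t_start_s = 0, duration_s = 10)
  expect_true(all(silent$series == 0))
})

test_that("periodicity: square wave recovered, white noise and constants rejected", {
  sq <- rep(c(rep(1, 25), rep(0, 25)), 12)       # 0.2 Hz at 10 Hz sampling
  p <- periodicity(sq, 10)
  expect_true(p$autocorrelation$detected)
  expect_true(p$welch$detected)
  expect_lt(abs(p$autocorrelation$period_s - 5), 0.1)
  expect_lt(abs(p$welch$period_s - 5), 0.1)
  expect_gt(p$autocorrelation$peak_value, p$autocorrelation$detection_threshold)
  pc <- periodicity(rep(0.4, 100), 10)
  expect_false(pc$autocorrelation$detected)
  expect_identical(pc$autocorrelation$flag, "zero_variance")
  set.seed(14)
  false_rate <- mean(replicate(200, {
    r <- periodicity(runif(600), 10)
    r$autocorrelation$detected || r$welch$detected
  }))
  expect_lte(false_rate, 0.05)
  expect_error(periodicity(1:5, 10), "at least 10")
})

test_that("simulated network-event period is recovered by both methods", {
  s <- simulate_recording(simulation_config(seed = 206, duration_s = 300))
  filt <- spike_band_filter(savgol_smooth(s$recording, window_points = 5),
                            300, 2000)
  trains <- detect_spikes(filt)
  nsp <- network_spiking_percentage(trains, t_start_s = 0, duration_s = 300)
  # peaks of the series align with true event times to within one bin
  ev_bins <- round(s$truth$event_times * nsp$fs_hz)
  near_ev <- vapply(ev_bins, function(b)
    max(nsp$series[pmax(1, b - 1):pmin(length(nsp$series), b + 2)]), numeric(1))
  expect_gt(min(near_ev), 0.8)
  p <- periodicity(nsp$series, nsp$fs_hz)
  expect_lt(abs(p$autocorrelation$period_s - 5), 0.1)
  expect_lt(abs(p$welch$period_s - 5), 0.1)
})
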