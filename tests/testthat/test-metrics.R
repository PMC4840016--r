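test_that("rpower is zero for perfect correction and one for doubled truth", {
  sim <- small_sim(fs_target = 512, seed = 2)
  ev <- sim$events
  tr <- sim$truth
  expect_equal(rpower(tr, tr, ev), rep(0, nrow(tr)))
  expect_equal(rpower(2 * tr, tr, ev), rep(1, nrow(tr)), tolerance = 1e-12)
})

test_that("rpower of the uncorrected signal equals the direct power ratio", {
  sim <- small_sim(fs_target = 1024, seed = 6)
  ev <- sim$events
  wlen <- round(0.010 * sim$fs)
  got <- rpower(sim$with_artifact, sim$truth, ev)
  # brute force from the generated components
  want <- vapply(seq_len(nrow(sim$truth)), function(ch) {
    mean(vapply(ev$onsets, function(o) {
      a <- (sim$with_artifact - sim$truth)[ch, o:(o + wlen)]
      d <- sim$truth[ch, o:(o + wlen)]
      mean(a^2) / mean(d^2)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("rpower is scale invariant and flags zero-power windows", {
  sim <- small_sim(fs_target = 512, seed = 2)
  r1 <- rpower(sim$with_artifact, sim$truth, sim$events)
  r2 <- rpower(5 * sim$with_artifact, 5 * sim$truth, sim$events)
  expect_equal(r1, r2, tolerance = 1e-12)
  z <- matrix(0, 1, 2000)
  expect_warning(rz <- rpower(z + 1, z, ccep_events(c(500, 1000), 512,
                                                    0.003, "biphasic")),
                 "zero truth power")
  expect_true(is.nan(rz) || is.na(rz))
})

test_that("first_peak_latency applies the first-above-threshold rule", {
  fs <- 1000
  x <- numeric(1200)
  onset <- 100
  # peaks at 5 ms (3 sd) and 30 ms (10 sd), noise sd = 1
  x[onset + 5] <- 3
  x[onset + 30] <- 10
  expect_equal(first_peak_latency(x, onset, fs, noise_sd = 1), 0.005)
  # below-threshold early peak is skipped
  x2 <- numeric(1200)
  x2[onset + 5] <- 1.5
  x2[onset + 30] <- 10
  expect_equal(first_peak_latency(x2, onset, fs, noise_sd = 1), 0.030)
  # negative deflections are found through the absolute value
  x3 <- numeric(1200); x3[onset + 12] <- -4
  expect_equal(first_peak_latency(x3, onset, fs, noise_sd = 1), 0.012)
  # flat signal, or peaks beyond the horizon, give NA
  expect_true(is.na(first_peak_latency(numeric(500), 100, fs, 1)))
  x4 <- numeric(1200); x4[onset + 150] <- 10
  expect_true(is.na(first_peak_latency(x4, onset, fs, 1, horizon_s = 0.1)))
})

test_that("lbias averages latency differences and handles missing peaks", {
  expect_equal(lbias(c(0.010, 0.012), c(0.010, 0.012)), 0)
  # one sample late at 512 Hz on every stimulation
  lc <- c(0.010, 0.012) + 1 / 512
  expect_equal(lbias(lc, c(0.010, 0.012)), 1 / 512, tolerance = 1e-12)
  expect_equal(1000 / 512, 1.953, tolerance = 1e-3)
  # mixed +/- one sample averaging to zero
  lt <- rep(0.01, 4)
  expect_equal(lbias(lt + c(1, -1, 1, -1) / 512, lt), 0)
  # missing corrected peaks are dropped; all-missing flags the channel
  expect_equal(lbias(c(NA, 0.012), c(0.010, 0.012)), 0)
  expect_true(is.na(lbias(c(NA, NA), c(0.01, 0.01))))
  expect_error(lbias(1, c(1, 2)), "equal length")
})

test_that("lbias of a pure time shift equals the shift exactly", {
  sim <- ccep_simulate(n_channels = 3, n_stims = 5, baseline_s = 1,
                       fs_target = 512, response_prob = 1, seed = 14,
                       noise_sd_range = c(0.01, 0.02))
  ch <- which(sim$channel_params$responding)[1]
  lt <- sim$true_latencies[sim$true_latencies$channel == ch, ]
  for (k in c(1L, 3L)) {
    shifted <- c(numeric(k), sim$truth[ch, ])[seq_len(ncol(sim$truth))]
    lc <- vapply(sim$events$onsets[lt$stim], function(o)
      first_peak_latency(shifted, o, sim$fs, 0.02), numeric(1))
    expect_equal(lbias(lc, lt$latency_snap_s), k / sim$fs,
                 tolerance = 1e-12)
  }
})

test_that("performance summary pools qualifying channels per cell", {
  sc <- data.frame(
    fs = rep(c(512, 1024), each = 4),
    pulse_duration = 0.002,
    method = rep(c("model", "model", "average", "average"), 2),
    channel = 1:8,
    responding = TRUE,
    class = c("fast", "fast", "fast", "slow", "fast", "fast", "fast", "fast"),
    true_peak_latency_s = c(0.005, 0.009, 0.004, 0.030,
                            0.002, 0.015, 0.006, 0.008),
    rpower = c(0.1, 0.3, 0.5, 0.2, 0.05, 0.2, 1.0, 1.4),
    lbias_s = c(0.001, 0.002, 0.003, 0.001, 0, 0.004, 0.002, NA),
    n_peaks = 5)
  tab <- summarize_performance(sc)
  expect_s3_class(tab, "ccep_performance")
  # slow and >10 ms channels excluded
  m512 <- tab[tab$fs == 512 & tab$method == "model", ]
  expect_equal(m512$n_channels, 2)
  expect_equal(m512$rpower_median, 0.2)
  expect_equal(m512$lbias_median_ms, 1.5)
  # single-channel cell: median = value, sd = NA-free zero denominator
  a512 <- tab[tab$fs == 512 & tab$method == "average", ]
  expect_equal(a512$n_channels, 1)
  expect_equal(a512$rpower_median, 0.5)
  # channels with no detectable peak are dropped from the LBias summary
  a1024 <- tab[tab$fs == 1024 & tab$method == "average", ]
  expect_equal(a1024$lbias_median_ms, 2)
  # truth-vs-truth scores give an all-zero table
  sc0 <- sc; sc0$rpower <- 0; sc0$lbias_s <- 0
  tab0 <- summarize_performance(sc0)
  expect_true(all(tab0$rpower_median == 0 & tab0$lbias_median_ms == 0))
  # summaries are permutation invariant
  perm <- sc[sample(nrow(sc)), ]
  expect_equal(summarize_performance(perm), tab, ignore_attr = TRUE)
})

test_that("score_correction returns coherent per-channel rows", {
  sim <- small_sim(fs_target = 1024, seed = 10)
  fit <- ccep_correct(sim$with_artifact, sim$events, method = "model",
                      rc_grid = rc_grid_default(per_decade = 3))
  sc <- score_correction(fit, sim)
  expect_equal(nrow(sc), nrow(sim$with_artifact))
  expect_true(all(sc$rpower >= 0, na.rm = TRUE))
  expect_true(all(is.na(sc$lbias_s[!sc$responding])))
  expect_true(all(sc$n_peaks[sc$responding] >= 0))
})
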