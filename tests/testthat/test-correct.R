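test_that("fit window length follows the 1.2 x pulse rule with a 3-sample floor", {
  expect_equal(fit_window_samples(0.003, 512), 3)    # ceil(1.843) < 3
  expect_equal(fit_window_samples(0.003, 2048), 8)   # ceil(7.37)
  expect_equal(fit_window_samples(1, 3), 4)          # ceil(3.6)
  expect_equal(fit_window_samples(0.001, 256), 3)
  expect_error(fit_window_samples(0, 512))
})

test_that("fit_stimulation recovers exact affine combinations and handles polarity", {
  # three mutually non-affine variant shapes
  V <- cbind(c(5, 1, 0.3, 0.1), c(4, 2, 1, 0.5), c(-3, 3, 2, 1))
  yk <- 2.5 * V[, 2] + 7
  fit <- fit_stimulation(yk, V)
  expect_equal(fit$shift, 1L)
  expect_equal(fit$coefficient, 2.5, tolerance = 1e-9)
  expect_equal(fit$intercept, 7, tolerance = 1e-9)
  expect_lt(fit$residual_power, 1e-18)

  neg <- fit_stimulation(-V[, 3], V)
  expect_equal(neg$shift, 2L)
  expect_equal(neg$coefficient, -1, tolerance = 1e-9)

  # degenerate variants are skipped; all-degenerate errors
  Vd <- cbind(rep(1, 4), V[, 1])
  expect_equal(fit_stimulation(V[, 1], Vd)$shift, 1L)
  expect_error(fit_stimulation(V[, 1], cbind(rep(1, 4), rep(0, 4))),
               "degenerate")
})

test_that("fit_stimulation on noise never beats the best fixed variant (brute force)", {
  stim <- ccep_stimulus("biphasic", 0.002)
  bank <- ccep_bank(stim, 512, rc_grid = c(3e-4), tail_duration = 0.05)
  V <- bank$variants[[1]][1:3, ]
  set.seed(42)
  for (i in 1:100) {
    y <- rnorm(3)
    fit <- fit_stimulation(y, V)
    # brute-force residual of every variant
    all_rss <- apply(V, 2, function(v) {
      if (var(v) < 1e-24) return(Inf)
      mean(resid(lm(y ~ v))^2)
    })
    expect_lte(fit$residual_power, min(all_rss) + 1e-12)
  }
})

test_that("select_channel_rc is an argmin with small-rc tie-breaking", {
  grid <- c(1e-5, 1e-4, 1e-3)
  expect_equal(select_channel_rc(c(3, 1, 2), grid), 1e-4)
  expect_equal(select_channel_rc(c(2, 2, 2), grid), 1e-5)
  expect_equal(select_channel_rc(c(1.04, 1, 2), grid, margin = 0.05), 1e-5)
  expect_error(select_channel_rc(numeric(0), numeric(0)), "empty")
  expect_error(select_channel_rc(c(1, 2), grid), "lengths")
})

test_that("model correction is exact on signals built from bank templates", {
  fs <- 1024
  stim <- ccep_stimulus("biphasic", 0.003)
  bank <- ccep_bank(stim, fs, rc_grid = rc_grid_default(per_decade = 2))
  onsets <- c(600, 1700, 2800, 3900)
  m <- 5000
  i_rc <- which(abs(bank$rc_grid - 1e-3) < 1e-12)  # identifiable at 1024 Hz
  tpl <- bank$variants[[i_rc]][, 13]
  amp <- 800
  x <- inject(tpl, onsets, m, scale = amp)
  ev <- ccep_events(onsets, fs, 0.003, "biphasic")
  fit <- ccep_correct(x, ev, method = "model", bank = bank)
  # pre-filter residual below 1e-9 of the artifact amplitude
  expect_lt(max(abs(residuals(fit))), 1e-9 * amp)
  expect_equal(unname(fit$selected_rc), 1e-3, tolerance = 1e-12)
  # identical alignment and coefficient at every stimulation, and the
  # reconstructed artifact matches the inserted one sample for sample
  expect_length(unique(fit$per_stim$shift), 1L)
  expect_equal(diff(range(fit$per_stim$coefficient)), 0, tolerance = 1e-9)
  expect_lt(max(abs(fitted(fit) - x)), 1e-9 * amp)
})

test_that("alternating artifact polarity yields alternating coefficients", {
  fs <- 1024
  bank <- ccep_bank(ccep_stimulus("biphasic", 0.003), fs,
                    rc_grid = rc_grid_default(per_decade = 2))
  onsets <- c(600, 1700, 2800, 3900)
  tpl <- bank$variants[[5]][, 3]
  x <- numeric(5000)
  for (i in seq_along(onsets)) {
    sgn <- (-1)^(i - 1)
    idx <- onsets[i]:(onsets[i] + length(tpl) - 1L)
    x[idx] <- x[idx] + sgn * 500 * tpl
  }
  fit <- ccep_correct(x, ccep_events(onsets, fs, 0.003, "biphasic"),
                      method = "model", bank = bank)
  expect_equal(sign(fit$per_stim$coefficient), c(1, -1, 1, -1))
  expect_lt(max(abs(residuals(fit))), 1e-9 * 500)
})

test_that("correction is equivariant under signal scaling", {
  # with identifiable time constants the whole pipeline is
  # scale-equivariant: all selection rules compare residuals relatively,
  # the regression and the filter are linear
  sim <- small_sim(fs_target = 1024, seed = 5, rc_range = c(1e-3, 1e-2))
  bank <- ccep_bank(ccep_stimulus("biphasic", sim$events$pulse_duration),
                    1024, rc_grid = rc_grid_default(per_decade = 5))
  f1 <- ccep_correct(sim$with_artifact, sim$events, method = "model",
                     bank = bank)
  f3 <- ccep_correct(3 * sim$with_artifact, sim$events, method = "model",
                     bank = bank)
  # sub-sample shift aliases are interchangeable for slow templates, so the
  # invariance is asserted on the outcome, not on the alias labels
  expect_equal(f3$per_stim$onset_used, f1$per_stim$onset_used)
  expect_lt(max(abs(fitted(f3) - 3 * fitted(f1))),
            1e-9 * max(abs(fitted(f3))))
  expect_lt(max(abs(f3$corrected - 3 * f1$corrected)),
            1e-9 * max(abs(f3$corrected)))
})

test_that("scaling the artifact alone scales coefficients, response preserved", {
  # noiseless slow-response channels with moderate time constants: the
  # artifact (pulse + tail <= ~15 ms) and the response (>= 20 ms) barely
  # overlap, the regime in which the artifact scale is separable
  sim <- ccep_simulate(n_channels = 4, n_stims = 6, baseline_s = 1,
                       fs_target = 1024, seed = 21, fast_fraction = 0,
                       response_prob = 1,
                       noise_sd_range = c(1e-6, 1e-6),
                       rc_range = c(1e-3, 3e-3))
  bank <- ccep_bank(ccep_stimulus("biphasic", sim$events$pulse_duration),
                    1024, rc_grid = rc_grid_default(per_decade = 5))
  art <- sim$with_artifact - sim$truth
  f1 <- ccep_correct(sim$truth + art, sim$events, method = "model",
                     bank = bank)
  f2 <- ccep_correct(sim$truth + 2 * art, sim$events, method = "model",
                     bank = bank)
  # the artifact estimate doubles with the artifact ...
  expect_lt(max(abs(fitted(f2) - 2 * fitted(f1))),
            0.01 * max(abs(fitted(f2))))
  # ... while the corrected response is essentially unchanged
  resp_amp <- sim$channel_params$response_amplitude
  win <- unlist(lapply(sim$events$onsets,
                       function(o) (o + 15):(o + 46)))  # 15-45 ms
  dmax <- apply(abs(f2$corrected[, win] - f1$corrected[, win]), 1L, max)
  expect_lt(max(dmax / resp_amp), 0.1)
})

test_that("average correction removes identical artifacts but not varying ones", {
  fs <- 512
  onsets <- c(300, 900, 1500, 2100)
  m <- 2700
  # the first window sample acts as the baseline reference, so an exactly
  # removable artifact starts one sample after the onset sample
  tpl <- c(0, 400, -300, 80, 30)
  x <- inject(tpl, onsets, m)
  ev <- ccep_events(onsets, fs, 0.006, "biphasic")
  fit <- ccep_correct(x, ev, method = "average")
  win <- unlist(lapply(onsets, function(o) o:(o + 3)))
  expect_lt(max(abs(residuals(fit)[win])), 1e-9)

  # artifact varying across stimulations leaves a nonzero residual
  x2 <- x
  x2[onsets[2] + 0:4] <- 2 * tpl
  fit2 <- ccep_correct(x2, ev, method = "average")
  expect_gt(max(abs(residuals(fit2)[win])), 10)

  # alternating polarity cancels in the average: correction ineffective
  x3 <- numeric(m)
  for (i in seq_along(onsets))
    x3[onsets[i] + 0:4] <- (-1)^i * tpl
  fit3 <- ccep_correct(x3, ev, method = "average")
  expect_equal(max(abs(fitted(fit3))), 0, tolerance = 1e-9)
})

test_that("average correction warns on a single stimulation", {
  ev <- ccep_events(100, 512, 0.003, "biphasic")
  expect_warning(ccep_correct(rnorm(500), ev, method = "average"),
                 "single stimulation")
})

test_that("low-pass filter preserves DC and the passband, attenuates above cutoff", {
  fs <- 1024
  tt <- seq(0, 2, by = 1 / fs)
  expect_equal(lowpass90(rep(2.5, 300), fs), rep(2.5, 300), tolerance = 1e-6)
  hi <- sin(2 * pi * 150 * tt)
  hi_f <- lowpass90(hi, fs)
  mid <- seq(200, length(tt) - 200)
  expect_lt(max(abs(hi_f[mid])) / 1, 10^(-20 / 20))   # >= 20 dB down
  lo <- sin(2 * pi * 10 * tt)
  lo_f <- lowpass90(lo, fs)
  expect_lt(max(abs(lo_f[mid] - lo[mid])), 0.01)      # < 1% change
  expect_warning(lowpass90(rnorm(100), 150), "clipped")
})

test_that("onset detection finds simulator onsets within one sample", {
  sim <- ccep_simulate(n_channels = 6, n_stims = 8, baseline_s = 2,
                       fs_target = 1024, seed = 9,
                       artifact_amp_range = c(1000, 5000))
  ev <- detect_onsets(sim$with_artifact, sim$fs, expected_rate = 1,
                      pulse_duration = sim$events$pulse_duration)
  expect_length(ev$onsets, length(sim$events$onsets))
  expect_true(all(abs(ev$onsets - sim$events$onsets) <= 1))
  expect_warning(e0 <- detect_onsets(rep(0, 4000), 1024), "no stimulation")
  expect_length(e0$onsets, 0)
  expect_error(detect_onsets(rnorm(100), 512, k = 0), "'k'")
})

test_that("samples far from onsets are changed only by the filter", {
  sim <- small_sim(fs_target = 512, seed = 13)
  bank <- ccep_bank(ccep_stimulus("biphasic", sim$events$pulse_duration),
                    512, rc_grid = rc_grid_default(per_decade = 3))
  fit <- ccep_correct(sim$with_artifact, sim$events, method = "model",
                      bank = bank)
  # outside the template spans the fitted artifact is exactly zero, and the
  # corrected signal differs from the raw one only through the low-pass
  # (allowing ~80 ms for the zero-phase filter impulse to ring out)
  far <- rep(TRUE, ncol(sim$with_artifact))
  L <- 1 + ceiling((bank$tail_duration + 0.004) * 512)
  for (o in sim$events$onsets)
    far[max(1, o - 2):min(o + L + 2, length(far))] <- FALSE
  expect_equal(max(abs(fitted(fit)[, far])), 0)
  far_f <- rep(TRUE, ncol(sim$with_artifact))
  for (o in sim$events$onsets)
    far_f[max(1, o - 45):min(o + L + 45, length(far_f))] <- FALSE
  filt_only <- lowpass90(sim$with_artifact, 512)
  expect_lt(max(abs(fit$corrected[, far_f] - filt_only[, far_f])), 1e-3)
})

test_that("stimulations too close to the signal edge are flagged and skipped", {
  fs <- 512
  bank <- ccep_bank(ccep_stimulus("biphasic", 0.003), fs,
                    rc_grid = c(1e-4, 1e-3))
  tpl <- bank$variants[[1]][, 1]
  x <- inject(tpl, c(300, 999), 1000, scale = 100)  # second one truncated
  ev <- ccep_events(c(300, 999), fs, 0.003, "biphasic")
  expect_warning(fit <- ccep_correct(x, ev, method = "model", bank = bank),
                 "too close")
  expect_equal(fit$per_stim$stim, 1L)
})
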