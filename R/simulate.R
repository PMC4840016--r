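#' Simulate CCEP recordings with known ground truth
#'
#' Generates synthetic intracranial EEG stimulation runs in which the
#' observed signal decomposes, per channel \code{i} and stimulation
#' \code{s}, as \code{Da = D + artifact} with \code{D = response + noise}:
#'
#' \itemize{
#' \item \strong{Artifact}: RC electrode--tissue model output
#'   (\code{\link{ccep_artifact}}) with a per-channel time constant drawn
#'   log-uniformly from \code{rc_range}, random amplitude and polarity, so
#'   that shape, amplitude and polarity change across channels.
#' \item \strong{Response}: present with probability \code{response_prob};
#'   a single raised-cosine (one cosine cycle) deflection. Fast responses
#'   (fraction \code{fast_fraction} of responding channels) have
#'   frequencies 50--70 Hz and first-peak latencies 1--20 ms (truncated so
#'   the onset never precedes the stimulation onset); slow responses have
#'   frequencies 20--50 Hz and peak latencies 20--40 ms. The cosine period
#'   is jittered by less than 10\% across successive stimulations of a
#'   channel, while across channels period (up to 66\%) and amplitude (up
#'   to 100\%) vary widely, with random polarity. The response amplitude is
#'   partially proportional to the artifact amplitude and always at least
#'   three times the channel noise SD so peaks remain detectable.
#' \item \strong{Noise}: Gaussian, zero mean, per-channel SD drawn
#'   uniformly from \code{noise_sd_range} (microvolts).
#' }
#'
#' Deterministic components are built at the master rate \code{fs_master}
#' and decimated to \code{fs_target} with a random per-channel phase
#' shift; in addition each stimulation pulse lands at a random sub-sample
#' phase of the recording grid (the stimulator clock is not synchronized
#' with the acquisition system), so the sampled artifact shape is not
#' reproducible between pulses. The white noise, whose distribution is
#' invariant under decimation, is added at the target rate.
#'
#' @param n_channels number of channels (default 30).
#' @param response_prob probability a channel carries a response (0.5).
#' @param fast_fraction fraction of responding channels with fast
#'   responses (default 0.6, chosen so roughly 28\% of all responding
#'   channels carry an early fast response with a true peak at or before
#'   10 ms; see the package vignette).
#' @param baseline_s pre-stimulation baseline (default 5 s).
#' @param n_stims number of stimulations (default 40).
#' @param stim_rate stimulation rate in Hz (default 1).
#' @param fs_master master simulation rate (default 50 kHz).
#' @param fs_target recording rate in Hz (256, 512, 1024, 2048 or 4096 in
#'   the reference protocol; any rate below \code{fs_master} is accepted).
#' @param pulse_duration,shape stimulus pulse description.
#' @param noise_sd_range per-channel noise SD range, microvolts.
#' @param artifact_amp_range per-channel artifact amplitude range,
#'   microvolts (log-uniform draw).
#' @param rc_range per-channel RC time-constant range, seconds
#'   (log-uniform draw).
#' @param response_alpha proportionality constant linking response
#'   amplitude to artifact amplitude (response amplitude =
#'   \code{max(3 * noise_sd, response_alpha * artifact_amplitude * u)},
#'   \code{u ~ U(0.5, 1.5)}).
#' @param period_jitter within-channel cosine period modulation bound
#'   (default 0.1, i.e. less than 10\%).
#' @param seed integer seed; the dataset is fully reproducible from it.
#'
#' @return Object of class \code{ccep_sim}: list with
#'   \code{with_artifact} and \code{truth} (channels-by-time matrices,
#'   microvolts), \code{events} (\code{\link{ccep_events}} at the
#'   recording rate), \code{true_latencies} (data frame: channel, stim,
#'   latency_s continuous, latency_snap_s snapped to the channel's actual
#'   sample grid), \code{channel_params} (per-channel draws), \code{fs},
#'   \code{fs_master}, \code{config}.
#' @examples
#' sim <- ccep_simulate(n_channels = 4, n_stims = 5, baseline_s = 1,
#'                      fs_target = 512, seed = 42)
#' dim(sim$with_artifact)
#' @export
ccep_simulate <- function(n_channels = 30, response_prob = 0.5,
                          fast_fraction = 0.6, baseline_s = 5,
                          n_stims = 40, stim_rate = 1, fs_master = 50000,
                          fs_target = 1024, pulse_duration = 0.003,
                          shape = c("biphasic", "monophasic"),
                          noise_sd_range = c(1, 50),
                          artifact_amp_range = c(200, 5000),
                          rc_range = c(1e-6, 1e-2),
                          response_alpha = 0.05, period_jitter = 0.1,
                          seed = NULL) {
  shape <- match.arg(shape)
  if (n_channels < 1 || n_stims < 1 || baseline_s < 0 || stim_rate <= 0)
    stop("invalid simulation configuration: counts and rates must be positive")
  if (response_prob < 0 || response_prob > 1 ||
      fast_fraction < 0 || fast_fraction > 1)
    stop("'response_prob' and 'fast_fraction' must be probabilities")
  if (fs_target > fs_master) stop("fs_target must not exceed fs_master")
  if (!is.null(seed)) set.seed(as.integer(seed))

  isi <- 1 / stim_rate
  dur_s <- baseline_s + n_stims * isi
  m_master <- round_half_up(dur_s * fs_master)
  r <- fs_master / fs_target
  k <- round_half_up(r)
  # common decimated length, valid for every shift in [0, k)
  m <- floor((m_master - 1 - (k - 1)) / r) + 1

  stim <- ccep_stimulus(shape, pulse_duration, fs_high = fs_master)
  tail_s <- max(0, min(5e-2, isi - pulse_duration))
  # 0-based nominal master onset indices
  onset_nom <- round_half_up((baseline_s + (seq_len(n_stims) - 1) * isi) *
                               fs_master)
  # the stimulator clock is not synchronized with the acquisition system:
  # each pulse lands at a random sub-sample phase of the recording grid,
  # so the sampled artifact shape is not reproducible between pulses
  onset0 <- onset_nom + sample.int(k, n_stims, replace = TRUE) - 1L
  # global nominal event samples at the recording rate (1-based)
  ev_onsets <- round_half_up(onset_nom / r) + 1L

  Da <- matrix(0, n_channels, m)
  D  <- matrix(0, n_channels, m)
  lat_rows <- vector("list", n_channels)
  cp <- data.frame(channel = seq_len(n_channels), rc = NA_real_,
                   artifact_amplitude = NA_real_, artifact_polarity = NA_real_,
                   shift = NA_integer_, noise_sd = NA_real_,
                   responding = NA, class = NA_character_,
                   base_freq = NA_real_, response_amplitude = NA_real_,
                   response_polarity = NA_real_, peak_latency = NA_real_)

  for (ch in seq_len(n_channels)) {
    rc <- 10^stats::runif(1, log10(rc_range[1]), log10(rc_range[2]))
    amp <- 10^stats::runif(1, log10(artifact_amp_range[1]),
                           log10(artifact_amp_range[2]))
    pol <- sample(c(-1, 1), 1)
    shift <- sample.int(k, 1) - 1L
    noise_sd <- stats::runif(1, noise_sd_range[1], noise_sd_range[2])
    responding <- stats::runif(1) < response_prob
    cls <- if (responding && stats::runif(1) < fast_fraction) "fast" else "slow"

    art_tpl <- ccep_artifact(rc, stim, tail_duration = tail_s)$samples
    art_master <- numeric(m_master)
    la <- length(art_tpl)
    for (s in seq_len(n_stims)) {
      i0 <- onset0[s] + 1L
      i1 <- min(i0 + la - 1L, m_master)
      art_master[i0:i1] <- art_master[i0:i1] +
        pol * amp * art_tpl[seq_len(i1 - i0 + 1L)]
    }

    resp_master <- numeric(m_master)
    resp_amp <- NA_real_; resp_pol <- NA_real_
    base_freq <- NA_real_; peak_lat <- NA_real_
    lat_s <- rep(NA_real_, n_stims)
    if (responding) {
      base_freq <- if (cls == "fast") stats::runif(1, 50, 70)
                   else stats::runif(1, 20, 50)
      peak_lat <- if (cls == "fast") stats::runif(1, 0.001, 0.020)
                  else stats::runif(1, 0.020, 0.040)
      resp_pol <- sample(c(-1, 1), 1)
      resp_amp <- max(3 * noise_sd,
                      response_alpha * amp * stats::runif(1, 0.5, 1.5))
      for (s in seq_len(n_stims)) {
        period <- (1 / base_freq) *
          stats::runif(1, 1 - period_jitter, 1 + period_jitter)
        t0 <- peak_lat - period / 2     # may precede the onset: truncated
        j0 <- onset0[s] + max(0L, ceiling(t0 * fs_master))
        j1 <- onset0[s] + floor((t0 + period) * fs_master)
        j1 <- min(j1, m_master - 1L)
        jj <- j0:j1
        tau <- jj / fs_master - onset0[s] / fs_master - t0
        resp_master[jj + 1L] <- resp_master[jj + 1L] +
          resp_pol * resp_amp * 0.5 * (1 - cos(2 * pi * tau / period))
        lat_s[s] <- peak_lat
      }
    }

    idx0 <- round_half_up(shift + (seq_len(m) - 1) * r)   # 0-based master
    D[ch, ]  <- resp_master[idx0 + 1L] + stats::rnorm(m, 0, noise_sd)
    Da[ch, ] <- D[ch, ] + art_master[idx0 + 1L]

    if (responding) {
      # snap the true latency to this channel's actual sample grid
      peak_master0 <- onset0 + lat_s * fs_master
      j_peak <- round_half_up((peak_master0 - shift) / r) + 1L
      lat_snap <- (j_peak - ev_onsets) / fs_target
      lat_rows[[ch]] <- data.frame(channel = ch, stim = seq_len(n_stims),
                                   latency_s = lat_s,
                                   latency_snap_s = lat_snap)
    }

    cp[ch, -1L] <- list(rc, amp, pol, shift, noise_sd, responding,
                        if (responding) cls else NA_character_,
                        base_freq, resp_amp, resp_pol, peak_lat)
  }

  events <- ccep_events(ev_onsets, fs_target, pulse_duration, shape,
                        rate_hz = stim_rate)
  structure(
    list(with_artifact = Da, truth = D, events = events,
         true_latencies = if (length(lat_rows)) do.call(rbind, lat_rows)
                          else NULL,
         channel_params = cp, fs = fs_target, fs_master = fs_master,
         config = list(n_channels = n_channels, response_prob = response_prob,
                       fast_fraction = fast_fraction, baseline_s = baseline_s,
                       n_stims = n_stims, stim_rate = stim_rate,
                       fs_master = fs_master, fs_target = fs_target,
                       pulse_duration = pulse_duration, shape = shape,
                       noise_sd_range = noise_sd_range,
                       artifact_amp_range = artifact_amp_range,
                       rc_range = rc_range, response_alpha = response_alpha,
                       period_jitter = period_jitter, seed = seed)),
    class = "ccep_sim")
}

#' @export
print.ccep_sim <- function(x, ...) {
  cat(sprintf(
    paste0("Simulated CCEP data set: %d channels x %d samples at %g Hz\n",
           "  %d stimulations at %g Hz (%s pulse, %.3g ms), %.3g s baseline\n",
           "  responding channels: %d of %d (%d fast, %d slow)\n"),
    nrow(x$with_artifact), ncol(x$with_artifact), x$fs,
    length(x$events$onsets), x$events$rate_hz, x$events$shape,
    1000 * x$events$pulse_duration, x$config$baseline_s,
    sum(x$channel_params$responding), nrow(x$channel_params),
    sum(x$channel_params$class == "fast", na.rm = TRUE),
    sum(x$channel_params$class == "slow", na.rm = TRUE)))
  invisible(x)
}

#' Single-cycle cosine response waveform
#'
#' Builds one response deflection as used by the simulator: a single
#' raised-cosine cycle of the given period, positioned so the peak falls at
#' \code{peak_latency} after the stimulation onset, truncated so the onset
#' of the deflection never precedes the stimulation onset.
#'
#' @param class \code{"fast"} (frequency 50--70 Hz, peak 1--20 ms) or
#'   \code{"slow"} (20--50 Hz, peak 20--40 ms); used for validation only
#'   when \code{frequency}/\code{peak_latency} are supplied.
#' @param frequency cosine frequency in Hz.
#' @param peak_latency peak latency in seconds after the onset.
#' @param amplitude peak amplitude (microvolts).
#' @param fs sampling rate of the returned waveform.
#' @param duration returned support length in seconds (default covers the
#'   deflection).
#' @return List with \code{waveform} (numeric vector starting at the
#'   stimulation onset) and \code{peak_latency}.
#' @export
ccep_response <- function(class = c("fast", "slow"), frequency = NULL,
                          peak_latency = NULL, amplitude = 1, fs = 50000,
                          duration = NULL) {
  class <- match.arg(class)
  if (is.null(frequency))
    frequency <- if (class == "fast") stats::runif(1, 50, 70)
                 else stats::runif(1, 20, 50)
  if (is.null(peak_latency))
    peak_latency <- if (class == "fast") stats::runif(1, 0.001, 0.020)
                    else stats::runif(1, 0.020, 0.040)
  period <- 1 / frequency
  t0 <- peak_latency - period / 2
  if (is.null(duration)) duration <- max(t0 + period, 0) + 1 / fs
  tt <- seq(0, duration, by = 1 / fs)
  wf <- numeric(length(tt))
  inside <- tt >= max(t0, 0) & tt <= t0 + period
  wf[inside] <- amplitude * 0.5 * (1 - cos(2 * pi * (tt[inside] - t0) / period))
  list(waveform = wf, peak_latency = peak_latency, frequency = frequency)
}
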