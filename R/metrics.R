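#' Residual artifact power ratio (RPower)
#'
#' Ratio between the artifactual power remaining after correction and the
#' response power, evaluated from each stimulation onset to 10 ms after
#' (the first-peak latency range of interest) and averaged over
#' stimulations:
#' \deqn{RPower_i = mean_s [ power(Dc_{i,s} - D_{i,s}) / power(D_{i,s}) ]}
#' with power the mean square over the window. Both signals must have been
#' through the same final low-pass so that in-band components cancel
#' exactly and the numerator isolates the artifact residual.
#'
#' @param corrected,truth numeric vectors or channels-by-time matrices of
#'   identical shape.
#' @param events a \code{\link{ccep_events}}.
#' @param fs sampling rate in Hz (default \code{events$fs}).
#' @param window_s evaluation window after onset, seconds (default 0.010).
#' @return Numeric vector, one RPower value per channel. Stimulations with
#'   zero truth power in the window are excluded with a warning.
#' @export
rpower <- function(corrected, truth, events, fs = events$fs,
                   window_s = 0.010) {
  if (!is.matrix(corrected)) corrected <- matrix(corrected, nrow = 1L)
  if (!is.matrix(truth)) truth <- matrix(truth, nrow = 1L)
  if (!identical(dim(corrected), dim(truth)))
    stop("'corrected' and 'truth' must have identical shapes")
  m <- ncol(truth)
  wlen <- round_half_up(window_s * fs)
  out <- numeric(nrow(truth))
  dropped <- 0L
  for (ch in seq_len(nrow(truth))) {
    ratios <- vapply(events$onsets, function(o) {
      i1 <- min(o + wlen, m)
      ct <- corrected[ch, o:i1]; tt <- truth[ch, o:i1]
      den <- mean(tt^2)
      if (den <= 0) return(NA_real_)
      mean((ct - tt)^2) / den
    }, numeric(1))
    if (anyNA(ratios)) dropped <- dropped + sum(is.na(ratios))
    out[ch] <- mean(ratios, na.rm = TRUE)
  }
  if (dropped > 0L)
    warning(sprintf("%d stimulation window(s) with zero truth power excluded",
                    dropped))
  out
}

#' First-peak latency
#'
#' Latency of the first local maximum of the absolute deflection after the
#' stimulation onset whose amplitude is at least \code{threshold} times the
#' noise standard deviation. The absolute deflection is used so that
#' negative-polarity responses are found. The search stops
#' \code{horizon_s} after the onset.
#'
#' @param x numeric vector (one channel), assumed approximately zero-mean
#'   at baseline (subtract a baseline estimate first if needed).
#' @param onset 1-based onset sample index.
#' @param fs sampling rate in Hz.
#' @param noise_sd noise standard deviation used for the amplitude
#'   threshold; estimate it from the pre-stimulus baseline (e.g.
#'   \code{\link{baseline_noise_sd}}).
#' @param threshold amplitude threshold in noise SD units (default 2).
#' @param horizon_s search horizon after the onset, seconds (default 0.1).
#' @return Latency in seconds, or \code{NA} if no qualifying peak exists.
#' @export
first_peak_latency <- function(x, onset, fs, noise_sd, threshold = 2,
                               horizon_s = 0.1) {
  if (onset < 1L || onset > length(x)) stop("'onset' outside the signal")
  i1 <- min(onset + round_half_up(horizon_s * fs), length(x))
  a <- abs(x[onset:i1])
  n <- length(a)
  if (n < 3L) return(NA_real_)
  for (i in 2:(n - 1L)) {
    if (a[i] >= a[i - 1L] && a[i] > a[i + 1L] &&
        a[i] >= threshold * noise_sd)
      return((i - 1L) / fs)
  }
  NA_real_
}

#' Robust baseline noise SD
#'
#' MAD-based standard deviation estimate from the pre-stimulus baseline
#' (all samples before the first onset), robust to occasional transients.
#'
#' @param x numeric vector or channels-by-time matrix.
#' @param events a \code{\link{ccep_events}}.
#' @return Numeric vector, one SD per channel.
#' @export
baseline_noise_sd <- function(x, events) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  i1 <- max(events$onsets[1L] - 1L, 2L)
  apply(x[, seq_len(i1), drop = FALSE], 1L, stats::mad)
}

#' First-peak latency bias (LBias)
#'
#' Mean over stimulations of the difference between the corrected-signal
#' first-peak latency and the true latency expected considering the
#' sampling frequency (the simulator's true latency snapped to the
#' channel's sample grid):
#' \deqn{LBias_i = mean_s ( lc_{i,s} - l_{i,s} )}
#'
#' @param corrected_latency numeric vector of per-stimulation corrected
#'   latencies in seconds (\code{NA} where no peak was detected).
#' @param true_latency matching vector of expected latencies in seconds.
#' @return Mean latency difference in seconds, or \code{NA} if no
#'   stimulation has both latencies (the channel is then flagged and
#'   excluded from summaries).
#' @export
lbias <- function(corrected_latency, true_latency) {
  if (length(corrected_latency) != length(true_latency))
    stop("latency vectors must have equal length")
  ok <- !is.na(corrected_latency) & !is.na(true_latency)
  if (!any(ok)) return(NA_real_)
  mean(corrected_latency[ok] - true_latency[ok])
}

#' Score a correction against simulator ground truth
#'
#' Computes per-channel RPower and LBias for a corrected simulated data
#' set. The truth signal is passed through the same low-pass as the
#' corrected signal before computing RPower, so in-band components cancel
#' and the numerator isolates the artifact residual. The peak-detection
#' threshold uses the standard deviation of the corrected signal before
#' the final low-pass (MAD over the pre-stimulus baseline): thresholding
#' at twice the signal's own SD, rather than the smaller SD of the
#' band-limited filtered noise, keeps filtered noise ripples and small
#' artifact residuals from qualifying as response peaks.
#'
#' @param correction a \code{\link{ccep_correction}} of the simulated
#'   \code{with_artifact} signal.
#' @param sim the generating \code{\link{ccep_simulate}} data set.
#' @return Data frame with one row per channel: \code{channel},
#'   \code{responding}, \code{class}, \code{true_peak_latency_s},
#'   \code{rpower}, \code{lbias_s}, \code{n_peaks} (stimulations with a
#'   detected corrected peak).
#' @export
score_correction <- function(correction, sim) {
  stopifnot(inherits(correction, "ccep_correction"),
            inherits(sim, "ccep_sim"))
  fs <- sim$fs
  corr <- correction$corrected
  if (!is.matrix(corr)) corr <- matrix(corr, nrow = 1L)
  truth_f <- lowpass90(sim$truth, fs, cutoff = correction$cutoff)
  rp <- rpower(corr, truth_f, sim$events, fs)
  pre <- residuals(correction)              # corrected, before the low-pass
  if (!is.matrix(pre)) pre <- matrix(pre, nrow = 1L)
  nsd <- baseline_noise_sd(pre, sim$events)

  cp <- sim$channel_params
  lb <- rep(NA_real_, nrow(cp))
  npk <- rep(0L, nrow(cp))
  for (ch in seq_len(nrow(cp))) {
    if (!isTRUE(cp$responding[ch])) next
    lt <- sim$true_latencies[sim$true_latencies$channel == ch, ]
    lc <- vapply(sim$events$onsets[lt$stim], function(o)
      first_peak_latency(corr[ch, ], o, fs, nsd[ch]), numeric(1))
    npk[ch] <- sum(!is.na(lc))
    lb[ch] <- lbias(lc, lt$latency_snap_s)
  }
  data.frame(channel = cp$channel, responding = cp$responding,
             class = cp$class, true_peak_latency_s = cp$peak_latency,
             rpower = rp, lbias_s = lb, n_peaks = npk)
}

#' Summarize per-channel metrics into a performance table
#'
#' Pools per-channel scores across data sets and reports, per
#' (sampling frequency, pulse duration, method) cell, the median and
#' standard deviation of RPower and LBias over the qualifying channels.
#' Qualifying channels carry fast responses with a true peak latency of at
#' most \code{max_latency_s} (the early-response regime in which artifact
#' contamination matters most). Channels without any detectable corrected
#' peak are excluded from the LBias summaries.
#'
#' @param scores data frame of per-channel scores with columns
#'   \code{fs}, \code{pulse_duration}, \code{method}, plus the columns of
#'   \code{\link{score_correction}}.
#' @param max_latency_s qualifying true-peak latency bound (default 0.010).
#' @return Data frame of class \code{ccep_performance}, one row per cell:
#'   \code{fs}, \code{pulse_duration}, \code{method}, \code{n_channels},
#'   \code{rpower_median}, \code{rpower_sd}, \code{lbias_median_ms},
#'   \code{lbias_sd_ms}. Empty cells are omitted with a warning.
#' @export
summarize_performance <- function(scores, max_latency_s = 0.010) {
  q <- scores[!is.na(scores$class) & scores$class == "fast" &
                scores$true_peak_latency_s <= max_latency_s, , drop = FALSE]
  cells <- unique(q[, c("fs", "pulse_duration", "method")])
  if (nrow(cells) == 0L) {
    warning("no qualifying channels in any cell")
    return(structure(data.frame(), class = c("ccep_performance",
                                             "data.frame")))
  }
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cc <- q[q$fs == cells$fs[i] &
              q$pulse_duration == cells$pulse_duration[i] &
              q$method == cells$method[i], , drop = FALSE]
    lb <- cc$lbias_s[!is.na(cc$lbias_s)]
    data.frame(fs = cells$fs[i], pulse_duration = cells$pulse_duration[i],
               method = cells$method[i], n_channels = nrow(cc),
               rpower_median = stats::median(cc$rpower, na.rm = TRUE),
               rpower_sd = stats::sd(cc$rpower[!is.na(cc$rpower)]),
               lbias_median_ms = 1000 * stats::median(lb),
               lbias_sd_ms = 1000 * stats::sd(lb))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$fs, out$pulse_duration, out$method), ]
  rownames(out) <- NULL
  structure(out, class = c("ccep_performance", "data.frame"))
}

#' @export
print.ccep_performance <- function(x, ...) {
  cat("CCEP correction performance (median / SD over qualifying channels)\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write a performance table
#'
#' @param perf a \code{ccep_performance} table.
#' @param path output path; \code{.json} extension selects JSON, anything
#'   else tab-separated text.
#' @export
write_performance <- function(perf, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(perf), path, digits = NA,
                         auto_unbox = TRUE)
  } else {
    utils::write.table(as.data.frame(perf), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
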