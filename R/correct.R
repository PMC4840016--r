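#' Stimulation event list
#'
#' @param onsets 1-based sample indices of stimulation onsets at the
#'   recording rate, strictly increasing.
#' @param fs recording rate in Hz.
#' @param pulse_duration stimulus pulse duration in seconds.
#' @param shape pulse shape, \code{"biphasic"} or \code{"monophasic"}.
#' @param rate_hz nominal stimulation frequency (default 1 Hz).
#' @return Object of class \code{ccep_events}.
#' @export
ccep_events <- function(onsets, fs, pulse_duration,
                        shape = c("biphasic", "monophasic"), rate_hz = 1) {
  shape <- match.arg(shape)
  onsets <- as.integer(onsets)
  if (length(onsets) && is.unsorted(onsets, strictly = TRUE))
    stop("'onsets' must be strictly increasing")
  if (any(onsets < 1L)) stop("'onsets' must be positive sample indices")
  structure(list(onsets = onsets, fs = fs, pulse_duration = pulse_duration,
                 shape = shape, rate_hz = rate_hz),
            class = "ccep_events")
}

#' @export
print.ccep_events <- function(x, ...) {
  cat(sprintf("%d stimulation events at %g Hz recording rate (%s, %.3g ms, nominal %g Hz)\n",
              length(x$onsets), x$fs, x$shape, 1000 * x$pulse_duration,
              x$rate_hz))
  invisible(x)
}

#' Regression fit window length
#'
#' The artifact template is fitted over a window of 1.2 times the pulse
#' duration, or at least 3 samples: the pulse part of the signal is much
#' less likely to be influenced by the actual physiological response than
#' the slow capacitive decay, which can be confounded with an early
#' response.
#'
#' @param pulse_duration pulse duration in seconds.
#' @param fs recording rate in Hz.
#' @return Integer window length in samples: \code{max(ceil(1.2 * pulse_duration * fs), 3)}.
#' @export
fit_window_samples <- function(pulse_duration, fs) {
  stopifnot(pulse_duration > 0, fs > 0)
  max(ceiling(1.2 * pulse_duration * fs), 3L)
}

#' Zero-phase 90 Hz low-pass filter
#'
#' Forward-backward (zero-phase) Butterworth low-pass, 4th order per pass,
#' cutoff 90 Hz, used as the final step of both correction methods to
#' remove residual high-frequency components. Zero-phase filtering is used
#' so that no latency shift is introduced into the corrected responses. DC
#' gain is 1.
#'
#' @param x numeric vector, or channels-by-time matrix.
#' @param fs sampling rate in Hz. If \code{fs <= 2 * cutoff} the cutoff is
#'   clipped to \code{0.45 * fs} with a warning.
#' @param cutoff cutoff frequency in Hz (default 90).
#' @return Filtered signal, same shape as \code{x}.
#' @export
lowpass90 <- function(x, fs, cutoff = 90) {
  stopifnot(fs > 0, cutoff > 0)
  if (fs <= 2 * cutoff) {
    warning(sprintf("fs = %g Hz cannot represent %g Hz; cutoff clipped to %g Hz",
                    fs, cutoff, 0.45 * fs))
    cutoff <- 0.45 * fs
  }
  bf <- signal::butter(4, cutoff / (fs / 2), type = "low")
  # odd-symmetric reflection padding suppresses the start-up transients of
  # the forward and backward passes (the filter state starts at zero)
  ff <- function(v) {
    n <- length(v)
    p <- min(n - 1L, 3L * ceiling(fs / cutoff) + 12L)
    ext <- c(2 * v[1L] - v[(p + 1L):2L], v, 2 * v[n] - v[(n - 1L):(n - p)])
    signal::filtfilt(bf, ext)[(p + 1L):(p + n)]
  }
  if (is.matrix(x)) {
    out <- x
    for (i in seq_len(nrow(x))) out[i, ] <- ff(x[i, ])
    out
  } else {
    ff(x)
  }
}

#' Detect stimulation onsets from the signal
#'
#' Flags samples whose absolute first difference exceeds a robust threshold
#' (the median of the absolute first differences plus \code{k} times their
#' median absolute deviation), and de-duplicates detections closer than half the expected
#' inter-stimulus interval. For multi-channel input the per-sample median
#' of the absolute difference across channels is used: the stimulation
#' artifact appears on (nearly) all channels simultaneously, while noise
#' excursions do not survive the median.
#'
#' @param x numeric vector or channels-by-time matrix.
#' @param fs recording rate in Hz.
#' @param expected_rate nominal stimulation rate in Hz (default 1).
#' @param k threshold multiplier (default 8; must be > 0).
#' @param pulse_duration,shape stimulus description stamped into the
#'   returned events.
#' @return A \code{\link{ccep_events}} (possibly empty, with a warning).
#' @export
detect_onsets <- function(x, fs, expected_rate = 1, k = 8,
                          pulse_duration = 0.003,
                          shape = c("biphasic", "monophasic")) {
  shape <- match.arg(shape)
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("'k' must be a positive threshold multiplier")
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  d <- abs(x[, -1L, drop = FALSE] - x[, -ncol(x), drop = FALSE])
  dagg <- apply(d, 2L, stats::median)
  thr <- stats::median(dagg) + k * stats::mad(dagg)
  cand <- which(dagg > thr) + 1L
  if (length(cand) == 0L) {
    warning("no stimulation onsets detected")
    return(ccep_events(integer(0), fs, pulse_duration, shape, expected_rate))
  }
  min_gap <- 0.5 / expected_rate * fs
  keep <- c(TRUE, diff(cand) > min_gap)
  ccep_events(cand[keep], fs, pulse_duration, shape, expected_rate)
}

#' Correct stimulation artifacts in CCEP recordings
#'
#' Fits and removes the stimulation artifact from each channel of an
#' intracranial EEG recording, per stimulation. Two methods are available:
#'
#' \describe{
#' \item{\code{"model"}}{Model-based correction. Every down-sampled variant
#'   of the RC electrode--tissue artifact template (all RC values of the
#'   grid, all sub-sample alignment shifts; see \code{\link{ccep_bank}}) is
#'   compared by linear regression (slope + intercept) to the recorded
#'   signal over a short window at each stimulation onset
#'   (\code{\link{fit_window_samples}}): the pulse part of the signal is
#'   far less influenced by the physiological response than the slow
#'   capacitive decay. For each RC value the best-fitting shift per
#'   stimulation is the one minimizing the in-window residual; the RC value
#'   itself is selected per channel by the residual power of the scaled
#'   template over its full support (pulse plus tail, where a wrong time
#'   constant mispredicts the data) summed over the stimulation run, with
#'   near-ties resolved to the smallest RC (\code{rc_margin}). The full
#'   scaled template is then subtracted at each onset with the
#'   per-stimulation fitted coefficient.}
#' \item{\code{"average"}}{Average-subtraction baseline. The per-channel
#'   template is the average over stimulations of the post-onset window of
#'   length pulse duration + 1 ms, after subtracting the first sample of
#'   each window as local baseline; the template is subtracted at each
#'   onset.}
#' }
#'
#' Both methods finish with a zero-phase 90 Hz low-pass
#' (\code{\link{lowpass90}}).
#'
#' Because the recording clock is generally not synchronized with the
#' stimulator, the sample at which the artifact actually starts may differ
#' from the nominal event sample by one sample; the model fit therefore
#' also searches onset offsets in \code{-onset_search:onset_search} and
#' keeps the best-fitting alignment per stimulation.
#'
#' @param x numeric vector or channels-by-time matrix (microvolts).
#' @param events a \code{\link{ccep_events}}.
#' @param fs recording rate in Hz; defaults to \code{events$fs}.
#' @param method \code{"model"} or \code{"average"}.
#' @param bank a precomputed \code{\link{ccep_bank}} (model method); built
#'   from \code{rc_grid}/\code{fs_high} and the event's stimulus description
#'   when omitted.
#' @param rc_grid RC grid used when building the bank.
#' @param fs_high master simulation rate for the bank (default 50 kHz).
#' @param onset_search onset alignment search radius in samples (default 1).
#' @param rc_margin relative margin for the per-channel RC selection: among
#'   RC values whose full-support residual power (summed over the
#'   stimulation run) is within this fraction of the minimum, the smallest
#'   RC is selected (default 0.05). Near-ties between tail models are thus
#'   resolved towards the least intervention; see Details.
#' @param cutoff low-pass cutoff in Hz (default 90).
#'
#' @return Object of class \code{ccep_correction} with elements
#'   \code{corrected} (filtered corrected signal, same shape as the input),
#'   \code{fitted_artifact} (the subtracted artifact estimate, unfiltered),
#'   \code{selected_rc} (per channel; NA for the average method),
#'   \code{per_stim} (data frame: channel, stim, onset, onset_used, shift,
#'   coefficient, intercept, residual_power), \code{method}, \code{fs},
#'   \code{events}, \code{input}.
#' @seealso \code{\link{ccep_bank}}, \code{\link{ccep_simulate}},
#'   \code{\link{rpower}}, \code{\link{lbias}}
#' @examples
#' sim <- ccep_simulate(n_channels = 2, n_stims = 4, baseline_s = 1,
#'                      fs_target = 512, seed = 1)
#' fit <- ccep_correct(sim$with_artifact, sim$events,
#'                     rc_grid = rc_grid_default(per_decade = 2))
#' fit
#' @export
ccep_correct <- function(x, events, fs = events$fs,
                         method = c("model", "average"),
                         bank = NULL, rc_grid = rc_grid_default(),
                         fs_high = 50000, onset_search = 1,
                         rc_margin = 0.05, cutoff = 90) {
  method <- match.arg(method)
  if (!inherits(events, "ccep_events"))
    stop("'events' must be a ccep_events object")
  vec_in <- !is.matrix(x)
  if (vec_in) x <- matrix(x, nrow = 1L)
  storage.mode(x) <- "double"
  n_ch <- nrow(x); m <- ncol(x)
  if (length(events$onsets) < 1L) stop("no stimulation events")

  if (method == "model") {
    if (is.null(bank)) {
      stim <- ccep_stimulus(events$shape, events$pulse_duration,
                            fs_high = fs_high)
      bank <- ccep_bank(stim, fs, rc_grid = rc_grid,
                        isi = 1 / events$rate_hz)
    }
    if (abs(bank$fs_target - fs) > 1e-9)
      stop("bank target rate does not match the recording rate")
    res <- correct_model(x, events, bank, onset_search, rc_margin)
  } else {
    res <- correct_average(x, events, fs)
  }

  corrected <- lowpass90(x - res$fitted_artifact, fs, cutoff = cutoff)
  if (vec_in) corrected_out <- drop(corrected) else corrected_out <- corrected

  structure(
    list(corrected = corrected_out, fitted_artifact = res$fitted_artifact,
         selected_rc = res$selected_rc, per_stim = res$per_stim,
         method = method, fs = fs, events = events, cutoff = cutoff,
         bank_params = res$bank_params,
         input = if (vec_in) drop(x) else x,
         call = match.call()),
    class = "ccep_correction")
}

# Model-based correction across all channels.
#
# Per stimulation, the regression (slope + intercept) is fitted on the short
# pulse window only, where the physiological response is least likely to
# contaminate the fit; the best sub-sample shift (and onset alignment) per
# stimulation is the one minimizing the in-window residual. The RC value is
# then selected per channel by the residual power of the scaled template
# evaluated over its FULL support (pulse plus capacitive tail), summed over
# the stimulation run: a 3-sample pulse window cannot discriminate time
# constants, but a wrong RC mispredicts the tail. Among RC values whose
# summed residual lies within `rc_margin` of the minimum, the smallest is
# taken (near-ties between tail models are resolved towards the least
# intervention, which prevents long-tail templates from absorbing the
# response on channels whose true artifact has no appreciable tail).
correct_model <- function(x, events, bank, onset_search, rc_margin = 0.05) {
  n_ch <- nrow(x); m <- ncol(x)
  w <- fit_window_samples(events$pulse_duration, bank$fs_target)
  L <- bank$n_samples
  if (w > L) stop("fit window longer than the bank templates")
  n_rc <- length(bank$rc_grid)
  offs <- seq.int(-onset_search, onset_search)
  offs <- offs[order(abs(offs), offs)]      # prefer the nominal onset on ties

  # per-rc centered variant windows and their sums of squares
  Vw  <- lapply(bank$variants, function(v) v[seq_len(w), , drop = FALSE])
  mv  <- lapply(Vw, colMeans)
  Vc  <- lapply(seq_len(n_rc), function(i) sweep(Vw[[i]], 2L, mv[[i]]))
  ssv <- lapply(Vc, function(v) colSums(v * v))
  good_shift <- lapply(ssv, function(s) which(s >= 1e-24))
  if (!any(lengths(good_shift) > 0L))
    stop("all template variants are degenerate within the fit window")

  fitted <- matrix(0, n_ch, m)
  sel_rc <- rep(NA_real_, n_ch)
  per_stim <- vector("list", n_ch)

  for (ch in seq_len(n_ch)) {
    sig <- x[ch, ]
    # candidate windows: (onset offset) x stimulation
    cand_stim <- rep(seq_along(events$onsets), each = length(offs))
    cand_start <- events$onsets[cand_stim] + rep(offs, length(events$onsets))
    ok <- cand_start >= 1L & cand_start + L - 1L <= m
    stim_ok <- vapply(seq_along(events$onsets),
                      function(s) any(ok[cand_stim == s]), logical(1))
    if (!all(stim_ok))
      warning(sprintf("channel %d: %d stimulation(s) too close to the signal edge, skipped",
                      ch, sum(!stim_ok)))
    cand_stim <- cand_stim[ok]; cand_start <- cand_start[ok]
    stims <- which(stim_ok)
    n_stim <- length(stims)
    if (n_stim == 0L) next
    colmap <- match(cand_stim, stims)

    Y  <- vapply(cand_start, function(s0) sig[s0:(s0 + w - 1L)], numeric(w))
    YF <- vapply(cand_start, function(s0) sig[s0:(s0 + L - 1L)], numeric(L))
    my <- colMeans(Y)
    Yc <- sweep(Y, 2L, my)
    syy <- colSums(Yc * Yc)

    full_res   <- matrix(Inf, n_rc, n_stim)  # full-support residual SS
    best_shift <- matrix(NA_integer_, n_rc, n_stim)
    best_col   <- matrix(NA_integer_, n_rc, n_stim)
    best_b     <- matrix(NA_real_, n_rc, n_stim)
    best_a     <- matrix(NA_real_, n_rc, n_stim)
    syyF  <- colSums(YF * YF)
    sumYF <- colSums(YF)
    for (i in seq_len(n_rc)) {
      good <- good_shift[[i]]
      if (!length(good)) next
      VFg <- bank$variants[[i]][, good, drop = FALSE]
      sxy <- crossprod(Vc[[i]][, good, drop = FALSE], Yc)   # shifts x cands
      rss <- sweep(-(sxy * sxy) / ssv[[i]][good], 2L, syy, "+")
      rss[rss < 0] <- 0
      # full-support residual of the scaled template for every candidate:
      # ||yF - b vF||^2, with b the in-window slope
      B <- sxy / ssv[[i]][good]
      fr <- sweep(-2 * B * crossprod(VFg, YF) +
                    B * B * colSums(VFg * VFg), 2L, syyF, "+")
      fr[fr < 0] <- 0
      # per stimulation: minimal in-window residual decides, exact and
      # near-exact ties (affinely equivalent variants) resolved by the
      # full-support residual
      for (st in seq_len(n_stim)) {
        js <- which(colmap == st)
        r_st <- rss[, js, drop = FALSE]
        m0 <- min(r_st)
        tied <- which(r_st <= m0 + 1e-9 * (m0 + max(syy[js]) * 1e-9))
        pick <- tied[which.min(fr[, js, drop = FALSE][tied])]
        gi <- (pick - 1L) %% nrow(r_st) + 1L      # shift index within good
        jb <- js[(pick - 1L) %/% nrow(r_st) + 1L] # candidate column
        sh <- good[gi]
        b <- sxy[gi, jb] / ssv[[i]][sh]
        best_shift[i, st] <- sh - 1L
        best_col[i, st] <- jb
        best_b[i, st] <- b
        best_a[i, st] <- my[jb] - b * mv[[i]][sh]
        full_res[i, st] <- fr[gi, jb]
      }
    }

    total <- rowSums(full_res)
    i_rc <- which(total <= (1 + rc_margin) * min(total))[1L]
    sel_rc[ch] <- bank$rc_grid[i_rc]

    # subtraction of the scaled full template for the selected rc
    v_full <- bank$variants[[i_rc]]
    rows <- data.frame(channel = ch, stim = stims,
                       onset = events$onsets[stims],
                       onset_used = cand_start[best_col[i_rc, ]],
                       shift = best_shift[i_rc, ],
                       coefficient = best_b[i_rc, ],
                       intercept = best_a[i_rc, ],
                       residual_power = full_res[i_rc, ] / L)
    for (t in seq_len(n_stim)) {
      s0 <- cand_start[best_col[i_rc, t]]
      s1 <- min(s0 + L - 1L, m)
      fitted[ch, s0:s1] <- fitted[ch, s0:s1] +
        best_b[i_rc, t] * v_full[seq_len(s1 - s0 + 1L), best_shift[i_rc, t] + 1L]
    }
    per_stim[[ch]] <- rows
  }

  list(fitted_artifact = fitted, selected_rc = sel_rc,
       per_stim = do.call(rbind, per_stim),
       bank_params = list(rc_grid = bank$rc_grid, fs_high = bank$fs_high,
                          n_shifts = bank$n_shifts,
                          tail_duration = bank$tail_duration))
}

# average-subtraction baseline method
correct_average <- function(x, events, fs) {
  n_ch <- nrow(x); m <- ncol(x)
  La <- max(ceiling((events$pulse_duration + 0.001) * fs), 1L)
  onsets <- events$onsets
  ok <- onsets + La - 1L <= m
  if (!all(ok)) {
    warning(sprintf("%d stimulation(s) too close to the signal edge, skipped",
                    sum(!ok)))
    onsets <- onsets[ok]
  }
  if (length(onsets) == 0L) stop("no usable stimulation windows")
  if (length(onsets) == 1L)
    warning("single stimulation: average template equals that window")

  fitted <- matrix(0, n_ch, m)
  per_stim <- vector("list", n_ch)
  for (ch in seq_len(n_ch)) {
    W <- matrix(vapply(onsets, function(o) x[ch, o:(o + La - 1L)],
                       numeric(La)), nrow = La)
    W <- sweep(W, 2L, W[1L, ])              # first sample as local baseline
    tpl <- rowMeans(W)
    res_pow <- colMeans((W - tpl)^2)
    for (t in seq_along(onsets)) {
      o <- onsets[t]
      fitted[ch, o:(o + La - 1L)] <- fitted[ch, o:(o + La - 1L)] + tpl
    }
    per_stim[[ch]] <- data.frame(
      channel = ch, stim = seq_along(onsets), onset = onsets,
      onset_used = onsets, shift = NA_integer_, coefficient = 1,
      intercept = NA_real_, residual_power = res_pow)
  }
  list(fitted_artifact = fitted, selected_rc = rep(NA_real_, n_ch),
       per_stim = do.call(rbind, per_stim),
       bank_params = list(window_samples = La))
}

#' Select the channel RC value from summed residuals
#'
#' Argmin over the RC grid of the residual power summed over the
#' stimulation run; ties (and, with \code{margin > 0}, near-ties within
#' the given relative margin of the minimum) are resolved to the smaller
#' RC value.
#'
#' @param summed_residuals numeric vector, one summed residual per RC value.
#' @param rc_grid the matching RC grid (increasing).
#' @param margin relative near-tie margin (default 0: plain argmin).
#' @return The selected RC value (seconds).
#' @export
select_channel_rc <- function(summed_residuals, rc_grid, margin = 0) {
  if (length(summed_residuals) == 0L) stop("empty residual vector")
  if (length(summed_residuals) != length(rc_grid))
    stop("residuals and rc_grid lengths differ")
  rc_grid[which(summed_residuals <=
                  (1 + margin) * min(summed_residuals))[1L]]
}

#' Fit one stimulation window against a set of template variants
#'
#' Ordinary least squares (slope + intercept) of the recorded window on
#' each variant; returns the variant minimizing the mean squared residual.
#' Ties are broken by the lowest shift index. Degenerate (constant)
#' variants are skipped.
#'
#' @param window numeric vector, the recorded fit window.
#' @param variants matrix with one template variant per column (rows =
#'   window samples).
#' @return List: \code{shift} (0-based best variant index),
#'   \code{coefficient}, \code{intercept}, \code{residual_power} (mean
#'   squared residual).
#' @export
fit_stimulation <- function(window, variants) {
  if (!is.matrix(variants)) variants <- matrix(variants, ncol = 1L)
  w <- length(window)
  if (nrow(variants) < w) stop("variants shorter than the window")
  V <- variants[seq_len(w), , drop = FALSE]
  mv <- colMeans(V)
  Vc <- sweep(V, 2L, mv)
  ssv <- colSums(Vc * Vc)
  good <- ssv >= 1e-24
  if (!any(good)) stop("all template variants are degenerate within the window")
  yc <- window - mean(window)
  sxy <- drop(crossprod(Vc[, good, drop = FALSE], yc))
  rss <- sum(yc * yc) - sxy^2 / ssv[good]
  rss[rss < 0] <- 0
  jg <- which.min(rss)
  j <- which(good)[jg]
  b <- sxy[jg] / ssv[j]
  a <- mean(window) - b * mv[j]
  list(shift = j - 1L, coefficient = b, intercept = a,
       residual_power = rss[jg] / w)
}
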