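#' Square-wave stimulation pulse
#'
#' Constructs the injected current waveform \code{u_i} used to drive the RC
#' electrode--tissue model: a monophasic square pulse of amplitude \code{+A}
#' over the full pulse duration, or a charge-balanced biphasic pulse
#' (\code{+A} over the first half, \code{-A} over the second half of the
#' total duration).
#'
#' @param shape \code{"biphasic"} or \code{"monophasic"}.
#' @param pulse_duration total stimulus duration in seconds, in (0, 0.1].
#' @param amplitude pulse amplitude (dimensionless template scale; the
#'   physical amplitude is absorbed later by the regression coefficient).
#' @param fs_high master simulation rate in Hz (default 50 kHz).
#'
#' @return An object of class \code{ccep_stimulus}: a list with the sampled
#'   waveform (\code{samples}, covering the pulse support only) and the
#'   generating parameters.
#' @examples
#' s <- ccep_stimulus("biphasic", pulse_duration = 0.002)
#' sum(s$samples)  # charge balanced: 0
#' @export
ccep_stimulus <- function(shape = c("biphasic", "monophasic"),
                          pulse_duration,
                          amplitude = 1,
                          fs_high = 50000) {
  shape <- match.arg(shape)
  if (!is.numeric(pulse_duration) || length(pulse_duration) != 1L ||
      !is.finite(pulse_duration) || pulse_duration <= 0 || pulse_duration > 0.1)
    stop("'pulse_duration' must be a single value in (0, 0.1] seconds")
  if (!is.numeric(fs_high) || length(fs_high) != 1L || fs_high <= 0)
    stop("'fs_high' must be a positive sampling rate in Hz")
  if (fs_high * pulse_duration < 2)
    stop("pulse too short: fs_high * pulse_duration must be >= 2 samples")

  if (shape == "monophasic") {
    n <- round_half_up(pulse_duration * fs_high)
    samples <- rep(amplitude, n)
  } else {
    n_half <- round_half_up(pulse_duration * fs_high / 2)
    samples <- c(rep(amplitude, n_half), rep(-amplitude, n_half))
  }
  structure(
    list(shape = shape, pulse_duration = pulse_duration,
         amplitude = amplitude, fs_high = fs_high, samples = samples),
    class = "ccep_stimulus")
}

#' RC electrode--tissue artifact model
#'
#' Forward-simulates the stimulation artifact as the resistor voltage of a
#' series RC circuit driven by the square current pulse \code{u_i}: the
#' capacitance summarizes capacitive effects at the electrode--tissue
#' interface, the resistance the passive resistivity of the tissue, and the
#' recorded artifact is \code{u_R = u_i - u_c} where the capacitor voltage
#' obeys \code{du_c/dt = (u_i - u_c) / rc}.
#'
#' The solution is computed piecewise-analytically: within each constant
#' input segment of level \code{A} starting from capacitor voltage
#' \code{v0}, \code{u_c(t) = A + (v0 - A) exp(-t/rc)}. This is exact at the
#' sample points and keeps \code{u_c} continuous across segment boundaries.
#' The output extends beyond the pulse by \code{tail_duration} to cover the
#' capacitive rebound with exponential decay.
#'
#' @param rc RC time constant in seconds (> 0; plausible interface values
#'   span 1e-6 to 1e-2 s).
#' @param stimulus a \code{\link{ccep_stimulus}}.
#' @param tail_duration post-pulse tail length in seconds; default
#'   \code{5 * rc} (the tail has decayed to below 1\% by then).
#'
#' @return An object of class \code{ccep_artifact}: list with \code{samples}
#'   (\code{u_R} at \code{fs_high}, first sample at t = 0), \code{uc} (the
#'   capacitor voltage trajectory), \code{rc}, \code{fs_high},
#'   \code{duration}.
#' @examples
#' a <- ccep_artifact(1e-4, ccep_stimulus("biphasic", 0.003))
#' @export
ccep_artifact <- function(rc, stimulus, tail_duration = 5 * rc) {
  if (!is.numeric(rc) || length(rc) != 1L || !is.finite(rc) || rc <= 0)
    stop("'rc' must be a single positive time constant in seconds")
  if (!inherits(stimulus, "ccep_stimulus"))
    stop("'stimulus' must be a ccep_stimulus object")
  if (!is.numeric(tail_duration) || length(tail_duration) != 1L ||
      tail_duration < 0)
    stop("'tail_duration' must be >= 0 seconds")

  fs <- stimulus$fs_high
  dt <- 1 / fs
  n_tail <- round_half_up(tail_duration * fs)
  ui <- c(stimulus$samples, rep(0, n_tail))

  uc <- numeric(length(ui))
  seg <- rle(ui)
  pos <- 1L
  v0 <- 0            # capacitor initially uncharged
  for (i in seq_along(seg$lengths)) {
    len <- seg$lengths[i]
    a <- seg$values[i]
    j <- seq_len(len) - 1L
    uc[pos + j] <- a + (v0 - a) * exp(-j * dt / rc)
    v0 <- a + (v0 - a) * exp(-len * dt / rc)
    pos <- pos + len
  }

  structure(
    list(rc = rc, samples = ui - uc, uc = uc, fs_high = fs,
         duration = length(ui) * dt, stimulus = stimulus),
    class = "ccep_artifact")
}

#' @export
print.ccep_stimulus <- function(x, ...) {
  cat(sprintf("CCEP stimulus: %s square pulse, %.3g ms, amplitude %g, %g kHz\n",
              x$shape, 1000 * x$pulse_duration, x$amplitude, x$fs_high / 1000))
  invisible(x)
}

#' @export
print.ccep_artifact <- function(x, ...) {
  cat(sprintf(
    "RC artifact template: rc = %.3g s, %d samples at %g kHz (%.3g ms)\n",
    x$rc, length(x$samples), x$fs_high / 1000, 1000 * x$duration))
  invisible(x)
}

#' Export an artifact template as delimited text
#'
#' Writes a two-column tab-separated table (\code{time_s}, \code{value}) for
#' external inspection.
#'
#' @param artifact a \code{\link{ccep_artifact}}.
#' @param path output file path.
#' @export
write_artifact <- function(artifact, path) {
  stopifnot(inherits(artifact, "ccep_artifact"))
  t_s <- (seq_along(artifact$samples) - 1L) / artifact$fs_high
  utils::write.table(
    data.frame(time_s = t_s, value = artifact$samples),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# round-half-up, avoiding the IEC banker's rounding of base round()
round_half_up <- function(x) floor(x + 0.5)
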