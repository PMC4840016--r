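# Shared helpers for the test suite. Fixtures are built in code; the RC
# circuit oracle integrates the state equation numerically and must stay
# independent of the package's piecewise-analytic solution.

# Explicit RK4 integration of du_c/dt = (u_i - u_c)/rc on an oversampled
# grid (zero-order-hold input), reporting u_R = u_i - u_c at the original
# sample points. For the linear decay towards a constant input level, one
# RK4 substep multiplies (u_c - u_i) by the degree-4 Taylor factor
# R(z) = 1 + z + z^2/2 + z^3/6 + z^4/24 with z = -h/rc, so the substeps
# within one sample collapse to a power of R(z); the oversampling factor is
# chosen so that h <= rc/12, keeping the RK4 truncation well under 1e-6.
rk4_artifact <- function(rc, stimulus, tail_duration, oversample = NULL) {
  fs <- stimulus$fs_high
  n_tail <- floor(tail_duration * fs + 0.5)
  ui <- c(stimulus$samples, rep(0, n_tail))
  if (is.null(oversample))
    oversample <- max(10, ceiling(12 / (rc * fs)))
  h <- 1 / (fs * oversample)
  z <- -h / rc
  rz <- 1 + z + z^2 / 2 + z^3 / 6 + z^4 / 24
  g <- rz^oversample                  # per-sample RK4 growth of (u_c - u_i)
  uc <- numeric(length(ui))
  v <- 0
  for (i in seq_along(ui)) {
    uc[i] <- v
    v <- ui[i] + (v - ui[i]) * g
  }
  ui - uc
}

# tiny simulation configuration used where full scale is not needed
small_sim <- function(fs_target = 512, ...) {
  ccep_simulate(n_channels = 4, n_stims = 6, baseline_s = 1,
                fs_target = fs_target, ...)
}

# place a template into a flat signal at given onsets
inject <- function(template, onsets, m, scale = 1) {
  x <- numeric(m)
  for (o in onsets) {
    i1 <- min(o + length(template) - 1L, m)
    x[o:i1] <- x[o:i1] + scale * template[seq_len(i1 - o + 1L)]
  }
  x
}
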