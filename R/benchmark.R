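#' Simulation benchmark over recording and stimulation parameters
#'
#' Replicates the simulation study design: for every cell of the
#' (sampling frequency, pulse duration) grid, simulates \code{n_sets}
#' ground-truth data sets, corrects them with each requested method, and
#' scores RPower and LBias on the qualifying early fast-response channels
#' (\code{\link{score_correction}}, \code{\link{summarize_performance}}).
#' Deterministic given \code{seed}: each (cell, set) pair gets a seed
#' derived from it, so method subsets see identical data.
#'
#' @param fs_targets recording rates in Hz (default 256, 512, 1024, 2048).
#' @param pulse_durations pulse durations in seconds (default 1, 2, 3 ms).
#' @param methods correction methods to run.
#' @param n_sets simulated data sets per cell (the full-scale protocol uses
#'   20; the default 5 keeps a full grid affordable on one CPU).
#' @param shape pulse shape (default biphasic).
#' @param seed integer master seed.
#' @param rc_grid RC grid for the correction bank.
#' @param ... further arguments passed to \code{\link{ccep_simulate}}
#'   (e.g. \code{n_channels}, \code{n_stims}).
#' @param verbose print progress to stderr.
#'
#' @return Object of class \code{ccep_benchmark}: list with
#'   \code{channels} (per-channel scores across all cells and sets) and
#'   \code{table} (the \code{\link{summarize_performance}} cell summary).
#' @examples
#' \donttest{
#' bm <- run_benchmark(fs_targets = 512, pulse_durations = 0.002,
#'                     n_sets = 1, n_stims = 10, seed = 1)
#' bm$table
#' }
#' @export
run_benchmark <- function(fs_targets = c(256, 512, 1024, 2048),
                          pulse_durations = c(0.001, 0.002, 0.003),
                          methods = c("model", "average"),
                          n_sets = 5, shape = "biphasic", seed = 1,
                          rc_grid = rc_grid_default(), ..., verbose = FALSE) {
  methods <- match.arg(methods, c("model", "average"), several.ok = TRUE)
  cells <- expand.grid(pulse_duration = pulse_durations, fs = fs_targets)
  all_scores <- list()
  for (ci in seq_len(nrow(cells))) {
    fs <- cells$fs[ci]; pd <- cells$pulse_duration[ci]
    bank <- NULL
    if ("model" %in% methods) {
      stim <- ccep_stimulus(shape, pd, fs_high = 50000)
      bank <- ccep_bank(stim, fs, rc_grid = rc_grid)
    }
    for (set in seq_len(n_sets)) {
      set_seed <- (as.integer(seed) + 7919L * ci + set) %% .Machine$integer.max
      sim <- ccep_simulate(fs_target = fs, pulse_duration = pd,
                           shape = shape, seed = set_seed, ...)
      for (meth in methods) {
        fit <- ccep_correct(sim$with_artifact, sim$events, method = meth,
                            bank = bank)
        sc <- score_correction(fit, sim)
        sc$fs <- fs; sc$pulse_duration <- pd; sc$method <- meth
        sc$set <- set
        all_scores[[length(all_scores) + 1L]] <- sc
      }
      if (verbose)
        message(sprintf("cell fs=%g pd=%gms set %d/%d done",
                        fs, 1000 * pd, set, n_sets))
    }
  }
  channels <- do.call(rbind, all_scores)
  structure(list(channels = channels,
                 table = summarize_performance(channels),
                 seed = seed, n_sets = n_sets),
            class = "ccep_benchmark")
}

#' @export
print.ccep_benchmark <- function(x, ...) {
  cat(sprintf("CCEP correction benchmark: %d sets per cell, seed %s\n\n",
              x$n_sets, format(x$seed)))
  print(x$table)
  invisible(x)
}
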