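#' Default RC time-constant grid
#'
#' Logarithmically spaced grid over the range of electrode--tissue time
#' constants that covers the artifact shapes seen in clinical recordings,
#' 1e-6 to 1e-2 s, at 10 points per decade (41 values by default).
#'
#' @param rc_min,rc_max grid range in seconds.
#' @param per_decade grid density (points per decade).
#' @return Strictly increasing numeric vector of RC values in seconds.
#' @export
rc_grid_default <- function(rc_min = 1e-6, rc_max = 1e-2, per_decade = 10) {
  stopifnot(rc_min > 0, rc_max > rc_min, per_decade >= 1)
  10^seq(log10(rc_min), log10(rc_max), by = 1 / per_decade)
}

#' Down-sample by decimation at a given phase shift
#'
#' Selects samples of a high-rate series at the target rate starting from
#' sample index \code{shift} (0-based). For an integer rate ratio \code{k}
#' this is every k-th sample starting at \code{shift}; for non-integer
#' ratios the source index of output sample j is
#' \code{round(shift + j * fs_high / fs_target)} so the accumulated phase
#' error never exceeds half a master sample. No anti-alias filter is
#' applied: the point of the shift enumeration is to reproduce exactly the
#' aliased shapes an unsynchronized acquisition system produces.
#'
#' @param x numeric vector sampled at \code{fs_high}.
#' @param fs_high,fs_target source and target rates in Hz.
#' @param shift 0-based phase shift, in \code{[0, round(fs_high/fs_target))}.
#' @param n_out number of output samples; default as many as fit.
#' @return Numeric vector of length \code{n_out}.
#' @export
downsample_shift <- function(x, fs_high, fs_target, shift, n_out = NULL) {
  k <- round_half_up(fs_high / fs_target)
  if (k < 1) stop("fs_target must not exceed fs_high")
  if (!is.numeric(shift) || length(shift) != 1L || shift < 0 || shift >= k)
    stop(sprintf("'shift' must be in [0, %d)", k))
  r <- fs_high / fs_target
  n <- length(x)
  if (is.null(n_out)) n_out <- floor((n - 1 - shift) / r) + 1
  if (n_out < 1) stop("series too short for this shift")
  idx <- round_half_up(shift + (seq_len(n_out) - 1) * r) + 1
  if (idx[n_out] > n)
    stop("requested 'n_out' exceeds available samples")
  x[idx]
}

#' Build the down-sampled artifact template bank
#'
#' Generates, for every RC value of the grid, the artifact template at the
#' master rate and all of its down-sampled variants obtained by shifting the
#' first retained sample recursively through one full target-rate sample
#' period. The bank enumerates every artifact shape that decimation of an
#' unsynchronized high-rate artifact can produce at the recording rate, and
#' is the basis the correction regresses against.
#'
#' @param stimulus a \code{\link{ccep_stimulus}} (its \code{fs_high} is the
#'   master rate).
#' @param fs_target recording rate in Hz (must not exceed the master rate).
#' @param rc_grid strictly increasing RC grid in seconds.
#' @param tail_duration template tail after the pulse, seconds; default
#'   \code{min(5 * max(rc_grid), isi - pulse_duration)} so the slowest
#'   capacitive rebound on the grid is covered without running into the
#'   next stimulation.
#' @param isi inter-stimulus interval in seconds used to cap the tail
#'   (default 1, i.e. 1 Hz stimulation).
#'
#' @return Object of class \code{ccep_bank}: list with \code{variants} (one
#'   \code{n_samples x n_shifts} matrix per RC value, all of identical
#'   size), \code{rc_grid}, \code{n_shifts}, \code{fs_target},
#'   \code{fs_high}, \code{stimulus}, \code{tail_duration}.
#' @examples
#' bank <- ccep_bank(ccep_stimulus("biphasic", 0.003), 512,
#'                   rc_grid = c(1e-4, 1e-3))
#' @export
ccep_bank <- function(stimulus, fs_target, rc_grid = rc_grid_default(),
                      tail_duration = NULL, isi = 1) {
  if (!inherits(stimulus, "ccep_stimulus"))
    stop("'stimulus' must be a ccep_stimulus object")
  if (length(rc_grid) < 1L) stop("'rc_grid' must be non-empty")
  if (is.unsorted(rc_grid, strictly = TRUE) || any(rc_grid <= 0))
    stop("'rc_grid' must be strictly increasing and positive")
  fs_high <- stimulus$fs_high
  if (fs_target > fs_high) stop("fs_target must not exceed the master rate")
  if (is.null(tail_duration))
    tail_duration <- max(0, min(5 * max(rc_grid),
                                isi - stimulus$pulse_duration))

  k <- round_half_up(fs_high / fs_target)
  r <- fs_high / fs_target
  templates <- lapply(rc_grid, function(rc)
    ccep_artifact(rc, stimulus, tail_duration = tail_duration)$samples)
  n_high <- length(templates[[1L]])
  # common output length valid for the largest shift
  n_out <- floor((n_high - 1 - (k - 1)) / r) + 1
  if (n_out < 1) stop("template shorter than one target-rate sample")

  variants <- lapply(templates, function(tpl) {
    m <- matrix(0, nrow = n_out, ncol = k)
    for (s in seq_len(k) - 1L)
      m[, s + 1L] <- downsample_shift(tpl, fs_high, fs_target, s, n_out)
    m
  })

  structure(
    list(rc_grid = rc_grid, fs_target = fs_target, fs_high = fs_high,
         n_shifts = k, n_samples = n_out, variants = variants,
         stimulus = stimulus, tail_duration = tail_duration),
    class = "ccep_bank")
}

#' @export
print.ccep_bank <- function(x, ...) {
  cat(sprintf(
    paste0("CCEP artifact template bank\n",
           "  stimulus: %s, %.3g ms pulse, master rate %g kHz\n",
           "  target rate: %g Hz, %d shifts x %d RC values = %d variants\n",
           "  variant length: %d samples (%.1f ms incl. %.1f ms tail)\n"),
    x$stimulus$shape, 1000 * x$stimulus$pulse_duration, x$fs_high / 1000,
    x$fs_target, x$n_shifts, length(x$rc_grid),
    x$n_shifts * length(x$rc_grid), x$n_samples,
    1000 * x$n_samples / x$fs_target, 1000 * x$tail_duration))
  invisible(x)
}

#' Serialize / restore a template bank
#'
#' Writes the bank as a delimited-text archive: a one-line JSON header with
#' the generating parameters followed by the stacked variant matrices
#' (tab-separated, one variant per column block). \code{read_bank} rebuilds
#' the bank from the header parameters and verifies the stored samples
#' against the rebuilt ones.
#'
#' @param bank a \code{\link{ccep_bank}}.
#' @param path archive path.
#' @rdname bank_io
#' @export
write_bank <- function(bank, path) {
  stopifnot(inherits(bank, "ccep_bank"))
  header <- jsonlite::toJSON(list(
    rc_grid = bank$rc_grid, fs_target = bank$fs_target,
    fs_high = bank$fs_high, n_shifts = bank$n_shifts,
    n_samples = bank$n_samples, tail_duration = bank$tail_duration,
    shape = bank$stimulus$shape,
    pulse_duration = bank$stimulus$pulse_duration,
    amplitude = bank$stimulus$amplitude), digits = NA, auto_unbox = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#ccep_bank ", header), con)
  flat <- do.call(cbind, bank$variants)
  utils::write.table(format(flat, digits = 17, trim = TRUE), con,
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @param check verify stored samples against a rebuild (default TRUE).
#' @rdname bank_io
#' @export
read_bank <- function(path, check = TRUE) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#ccep_bank "))
    stop("not a ccep_bank archive: ", path)
  h <- jsonlite::fromJSON(sub("^#ccep_bank ", "", first))
  stim <- ccep_stimulus(h$shape, h$pulse_duration, h$amplitude, h$fs_high)
  bank <- ccep_bank(stim, h$fs_target, rc_grid = h$rc_grid,
                    tail_duration = h$tail_duration)
  if (check) {
    flat <- as.matrix(utils::read.table(path, sep = "\t", skip = 1L))
    dimnames(flat) <- NULL
    stored <- do.call(cbind, bank$variants)
    if (max(abs(flat - stored)) > 1e-12 * max(abs(stored)))
      stop("bank archive does not match its header parameters")
  }
  bank
}
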