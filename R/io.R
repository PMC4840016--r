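#' Read a multichannel signal file
#'
#' Supports tab-delimited numeric text (mandatory header row, optional
#' first column \code{time_s} in seconds, one column per channel, '.'
#' decimal separator, '#' comment lines) and 16-bit EDF. Values are
#' returned in microvolts (EDF channels are rescaled by their physical
#' calibration).
#'
#' @param path input file.
#' @param format \code{"auto"} (by extension), \code{"delimited"} or
#'   \code{"edf"}.
#' @param fs sampling rate in Hz, required for delimited files without a
#'   time column.
#' @return List with \code{data} (channels-by-time matrix), \code{fs},
#'   \code{channel_names}.
#' @export
read_signals <- function(path, format = c("auto", "delimited", "edf"),
                         fs = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
              else "delimited"
  if (format == "edf") return(read_edf(path))

  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", check.names = FALSE)
  if (ncol(tab) < 1L) stop("no columns in ", path)
  bad <- which(!vapply(tab, is.numeric, logical(1)))
  if (length(bad))
    stop(sprintf("non-numeric column '%s' in %s", names(tab)[bad[1L]], path))
  nonfin <- which(!is.finite(as.matrix(tab)), arr.ind = TRUE)
  if (nrow(nonfin))
    stop(sprintf("non-finite value at row %d, column '%s' in %s",
                 nonfin[1L, 1L], names(tab)[nonfin[1L, 2L]], path))
  tcol <- which(names(tab) %in% c("time_s", "time"))
  if (length(tcol)) {
    tt <- tab[[tcol[1L]]]
    fs <- 1 / stats::median(diff(tt))
    tab <- tab[, -tcol[1L], drop = FALSE]
  } else if (is.null(fs)) {
    stop("delimited file has no time column; supply 'fs'")
  }
  list(data = t(as.matrix(tab)), fs = fs, channel_names = names(tab))
}

#' Write a multichannel signal file
#'
#' @param x channels-by-time matrix (microvolts).
#' @param fs sampling rate in Hz.
#' @param path output file.
#' @param format \code{"auto"}, \code{"delimited"} or \code{"edf"}.
#' @param channel_names channel labels.
#' @param meta named list recorded as provenance comment lines (delimited)
#'   or in the recording-id field (EDF), e.g. seed and configuration hash.
#' @export
write_signals <- function(x, fs, path, format = c("auto", "delimited", "edf"),
                          channel_names = NULL, meta = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
              else "delimited"
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(x)))
  if (format == "edf")
    return(write_edf(x, fs, path, channel_names, meta = meta))

  con <- file(path, "w")
  on.exit(close(con))
  for (line in provenance_lines(meta)) writeLines(line, con)
  df <- data.frame((seq_len(ncol(x)) - 1L) / fs, t(x), check.names = FALSE)
  names(df) <- c("time_s", channel_names)
  utils::write.table(format(df, digits = 10, trim = TRUE), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

provenance_lines <- function(meta) {
  meta <- c(list(generator = "ccepclean",
                 version = as.character(utils::packageVersion("ccepclean"))),
            meta)
  vapply(names(meta), function(k)
    sprintf("# %s: %s", k, paste(format(meta[[k]]), collapse = " ")),
    character(1))
}

# order-stable polynomial hash of a configuration list for provenance stamps
config_hash <- function(config) {
  txt <- paste(deparse(config[order(names(config))]), collapse = "")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Read / write stimulation events
#'
#' Tab-delimited event files with columns \code{onset_s},
#' \code{duration_s}, \code{label}; onsets in seconds from the start of
#' the recording, converted to sample indices at the recording rate.
#'
#' @param path event file path.
#' @param fs recording rate in Hz.
#' @param shape,rate_hz stimulus description for the returned events.
#' @rdname events_io
#' @export
read_events <- function(path, fs, shape = "biphasic", rate_hz = 1) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#")
  if (!all(c("onset_s", "duration_s") %in% names(tab)))
    stop("event file must have 'onset_s' and 'duration_s' columns")
  ccep_events(round_half_up(tab$onset_s * fs) + 1L, fs,
              pulse_duration = stats::median(tab$duration_s),
              shape = shape, rate_hz = rate_hz)
}

#' @param events a \code{\link{ccep_events}}.
#' @param meta provenance metadata list.
#' @rdname events_io
#' @export
write_events <- function(events, path, meta = NULL) {
  stopifnot(inherits(events, "ccep_events"))
  con <- file(path, "w")
  on.exit(close(con))
  for (line in provenance_lines(meta)) writeLines(line, con)
  df <- data.frame(onset_s = (events$onsets - 1L) / events$fs,
                   duration_s = events$pulse_duration,
                   label = sprintf("stim_%03d", seq_along(events$onsets)))
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a correction fit report
#'
#' JSON report with, per channel, the selected RC value and per
#' stimulation the onset used, shift, regression coefficient, intercept
#' and residual power.
#'
#' @param correction a \code{\link{ccep_correct}} result.
#' @param path output path.
#' @param meta provenance metadata list.
#' @export
write_fit_report <- function(correction, path, meta = NULL) {
  stopifnot(inherits(correction, "ccep_correction"))
  ps <- correction$per_stim
  chans <- lapply(sort(unique(ps$channel)), function(ch) {
    d <- ps[ps$channel == ch, , drop = FALSE]
    list(channel = ch, selected_rc = correction$selected_rc[ch],
         stimulations = lapply(seq_len(nrow(d)), function(i)
           list(stim = d$stim[i], onset = d$onset[i] - 1L,
                onset_used = d$onset_used[i] - 1L, shift = d$shift[i],
                coefficient = d$coefficient[i],
                intercept = d$intercept[i],
                residual_power = d$residual_power[i])))
  })
  jsonlite::write_json(
    list(method = correction$method, fs = correction$fs,
         meta = c(list(generator = "ccepclean"), meta),
         channels = chans),
    path, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}

# ---- minimal 16-bit EDF support -------------------------------------------
# Continuous EDF with 1 s data records and integer samples-per-record; this
# covers the package's own outputs and typical clinical exports at the
# rates handled here.

pad_field <- function(x, width) {
  s <- substr(format(x, trim = TRUE), 1L, width)
  formatC(s, width = -width)
}

write_edf <- function(x, fs, path, channel_names, meta = NULL) {
  ns <- nrow(x); m <- ncol(x)
  spr <- round_half_up(fs)
  if (abs(spr - fs) > 1e-9)
    stop("EDF writer requires an integer sampling rate")
  n_rec <- ceiling(m / spr)
  pad <- n_rec * spr - m
  if (pad > 0) x <- cbind(x, matrix(0, ns, pad))

  pmin_ <- pmax_ <- numeric(ns)
  dig <- matrix(0L, ns, n_rec * spr)
  for (i in seq_len(ns)) {
    rng <- max(abs(x[i, ]), 1)
    pmin_[i] <- -signif(rng * 1.01, 6); pmax_[i] <- signif(rng * 1.01, 6)
    dig[i, ] <- as.integer(round((x[i, ] - pmin_[i]) /
                                   (pmax_[i] - pmin_[i]) * 65535 - 32768))
  }

  rec_id <- paste(c("ccepclean",
                    if (!is.null(meta)) paste0(names(meta), "=",
                                               vapply(meta, function(v)
                                                 paste(format(v), collapse = ","),
                                                 character(1)))),
                  collapse = " ")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(pad_field(s, w), con, nchars = w,
                                 eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr(rec_id, 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(as.character(256 * (1 + ns)), 8); wr("", 44)
  wr(as.character(n_rec), 8); wr("1", 8); wr(as.character(ns), 4)
  for (i in seq_len(ns)) wr(channel_names[i], 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(format(pmin_[i]), 8)
  for (i in seq_len(ns)) wr(format(pmax_[i]), 8)
  for (i in seq_len(ns)) wr("-32768", 8)
  for (i in seq_len(ns)) wr("32767", 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(as.character(spr), 8)
  for (i in seq_len(ns)) wr("", 32)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    for (i in seq_len(ns))
      writeBin(dig[i, cols], con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                 # header length (recomputed)
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("EDF reader requires a single sampling rate across signals")
  fs <- spr[1L] / rec_dur
  out <- matrix(0, ns, n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                   endian = "little")
      out[i, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <-
        (d - dmin_[i]) / (dmax_[i] - dmin_[i]) * (pmax_[i] - pmin_[i]) +
        pmin_[i]
    }
  }
  list(data = out, fs = fs, channel_names = labels)
}

#' Export a simulated data set to disk
#'
#' Writes the signals (with artifact), the ground-truth signal, the event
#' list, and the true-latency table of a simulated set, all as delimited
#' text (or EDF for the signal files if \code{format = "edf"}).
#'
#' @param sim a \code{\link{ccep_simulate}} data set.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default \code{"set"}).
#' @param format signal format, \code{"delimited"} or \code{"edf"}.
#' @return Invisibly, the named vector of written paths.
#' @export
write_sim <- function(sim, dir, prefix = "set",
                      format = c("delimited", "edf")) {
  format <- match.arg(format)
  stopifnot(inherits(sim, "ccep_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "edf") ".edf" else ".tsv"
  meta <- list(seed = sim$config$seed, config = config_hash(sim$config))
  p <- c(signals = file.path(dir, paste0(prefix, "_signals", ext)),
         truth = file.path(dir, paste0(prefix, "_truth", ext)),
         events = file.path(dir, paste0(prefix, "_events.tsv")),
         latencies = file.path(dir, paste0(prefix, "_latencies.tsv")))
  write_signals(sim$with_artifact, sim$fs, p["signals"], format = format,
                meta = meta)
  write_signals(sim$truth, sim$fs, p["truth"], format = format, meta = meta)
  write_events(sim$events, p["events"], meta = meta)
  con <- file(p["latencies"], "w")
  for (line in provenance_lines(meta)) writeLines(line, con)
  lt <- sim$true_latencies
  if (is.null(lt))
    lt <- data.frame(channel = integer(0), stim = integer(0),
                     latency_s = numeric(0), latency_snap_s = numeric(0))
  utils::write.table(lt, con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  invisible(p)
}
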