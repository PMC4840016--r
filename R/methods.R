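#' @export
print.ccep_correction <- function(x, ...) {
  nch <- if (is.matrix(x$corrected)) nrow(x$corrected) else 1L
  cat(sprintf("CCEP artifact correction (%s method)\n", x$method))
  cat(sprintf("  %d channel(s), %d stimulation(s), fs = %g Hz, low-pass %g Hz\n",
              nch, length(x$events$onsets), x$fs, x$cutoff))
  if (x$method == "model") {
    rc <- x$selected_rc[!is.na(x$selected_rc)]
    if (length(rc))
      cat(sprintf("  selected RC range: %.3g - %.3g s\n", min(rc), max(rc)))
  }
  invisible(x)
}

#' Summarize a CCEP artifact correction
#'
#' @param object a \code{\link{ccep_correct}} result.
#' @param ... unused.
#' @return A list of class \code{summary.ccep_correction} with per-channel
#'   selected RC, median fitted coefficient, and median residual power.
#' @export
summary.ccep_correction <- function(object, ...) {
  ps <- object$per_stim
  agg <- do.call(rbind, lapply(split(ps, ps$channel), function(d)
    data.frame(channel = d$channel[1L],
               n_stims = nrow(d),
               coef_median = stats::median(d$coefficient),
               residual_power_median = stats::median(d$residual_power))))
  agg$selected_rc <- object$selected_rc[agg$channel]
  rownames(agg) <- NULL
  structure(list(method = object$method, fs = object$fs, channels = agg),
            class = "summary.ccep_correction")
}

#' @export
print.summary.ccep_correction <- function(x, ...) {
  cat(sprintf("CCEP artifact correction summary (%s method, fs = %g Hz)\n",
              x$method, x$fs))
  print.data.frame(x$channels, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
coef.ccep_correction <- function(object, ...) {
  ps <- object$per_stim
  nch <- length(unique(ps$channel))
  mat <- matrix(NA_real_, nch, max(ps$stim),
                dimnames = list(paste0("ch", sort(unique(ps$channel))),
                                NULL))
  mat[cbind(match(ps$channel, sort(unique(ps$channel))), ps$stim)] <-
    ps$coefficient
  mat
}

#' @export
fitted.ccep_correction <- function(object, ...) {
  object$fitted_artifact
}

#' Residuals of a CCEP artifact correction
#'
#' The corrected signal before the final low-pass: input minus the fitted
#' artifact estimate.
#' @param object a \code{\link{ccep_correct}} result.
#' @param ... unused.
#' @export
residuals.ccep_correction <- function(object, ...) {
  inp <- object$input
  if (!is.matrix(inp)) return(inp - drop(object$fitted_artifact))
  inp - object$fitted_artifact
}

#' Plot a corrected stimulation
#'
#' Overlays the raw and corrected signal around one stimulation of one
#' channel.
#'
#' @param x a \code{\link{ccep_correct}} result.
#' @param channel channel index (default 1).
#' @param stim stimulation index (default 1).
#' @param window_s plotted window after the onset, seconds (default 0.05).
#' @param ... passed to \code{matplot}.
#' @export
plot.ccep_correction <- function(x, channel = 1, stim = 1,
                                 window_s = 0.05, ...) {
  raw <- if (is.matrix(x$input)) x$input[channel, ] else x$input
  cor <- if (is.matrix(x$corrected)) x$corrected[channel, ] else x$corrected
  o <- x$events$onsets[stim]
  idx <- max(1L, o - round_half_up(0.01 * x$fs)):
    min(length(raw), o + round_half_up(window_s * x$fs))
  t_ms <- 1000 * (idx - o) / x$fs
  graphics::matplot(t_ms, cbind(raw[idx], cor[idx]), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "time from onset (ms)",
                    ylab = expression(paste("amplitude (", mu, "V)")), ...)
  graphics::abline(v = 0, lty = 3)
  graphics::legend("topright", c("raw", "corrected"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}
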