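#' Construct a multichannel waveform recording
#'
#' Container for uniformly sampled physiological signals: a numeric matrix
#' with one named column per channel, a constant sampling rate, a start
#' time (elapsed seconds convention, default 0), per-period protocol
#' annotations and injected-artifact annotations.
#'
#' @param channels numeric matrix, one column per channel, equal lengths by
#'   construction.
#' @param sampling_rate sampling frequency in Hz.
#' @param start_time recording start, seconds.
#' @param periods data frame of protocol periods (half-open
#'   \code{[start, end)} intervals in seconds), or \code{NULL}.
#' @param artifacts data frame of injected artifact intervals.
#' @return A \code{waveform_recording}.
#' @export
new_waveform_recording <- function(channels, sampling_rate, start_time = 0,
                                   periods = NULL, artifacts = NULL) {
  if (!is.matrix(channels) || !is.numeric(channels))
    stop("channels must be a numeric matrix")
  if (is.null(colnames(channels)))
    stop("channels must have column names")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (is.null(artifacts))
    artifacts <- data.frame(channel = character(), start = numeric(),
                            end = numeric(), type = character(),
                            stringsAsFactors = FALSE)
  dur <- nrow(channels) / sampling_rate
  if (!is.null(periods) && nrow(periods) &&
      (min(periods$start) < 0 || max(periods$end) > dur + 1e-9))
    stop("period annotations extend outside the recording span")
  structure(list(channels = channels, sampling_rate = sampling_rate,
                 start_time = start_time, periods = periods,
                 artifacts = artifacts),
            class = "waveform_recording")
}

#' @export
print.waveform_recording <- function(x, ...) {
  n <- nrow(x$channels)
  cat(sprintf("Waveform recording: %d samples x %d channels @ %g Hz (%.1f min)\n",
              n, ncol(x$channels), x$sampling_rate,
              n / x$sampling_rate / 60))
  cat("  channels:", paste(colnames(x$channels), collapse = ", "), "\n")
  if (!is.null(x$periods))
    cat(sprintf("  %d annotated periods, %d artifact intervals\n",
                nrow(x$periods), nrow(x$artifacts)))
  invisible(x)
}

#' @export
plot.waveform_recording <- function(x, channels = colnames(x$channels),
                                    from = 0, to = NULL, ...) {
  fs <- x$sampling_rate
  n <- nrow(x$channels)
  if (is.null(to)) to <- n / fs
  i <- seq(max(1, floor(from * fs) + 1), min(n, ceiling(to * fs)))
  t <- (i - 1) / fs
  old <- graphics::par(mfrow = c(length(channels), 1),
                       mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  for (ch in channels)
    graphics::plot(t, x$channels[i, ch], type = "l", xlab = "",
                   ylab = ch, ...)
  invisible(x)
}
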