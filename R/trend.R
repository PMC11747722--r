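#' Coarse-grain a recording to 0.1 Hz block averages
#'
#' Downsamples every channel by non-overlapping block averaging (default
#' 10 s blocks, i.e. 0.1 Hz). A block is valid only if at least half of its
#' raw samples are finite; the block mean is taken over the finite samples.
#' A trailing partial block is dropped.
#'
#' @param rec a \code{waveform_recording}.
#' @param block_s block width in seconds (default 10).
#' @return A \code{trend_series}: \code{time} (block end-times, s),
#'   \code{values} (blocks x channels matrix), \code{valid} (logical mask),
#'   \code{block_s}, and the recording's period annotations carried along.
#' @export
coarse_grain <- function(rec, block_s = 10) {
  stopifnot(inherits(rec, "waveform_recording"))
  fs <- rec$sampling_rate
  n_per <- fs * block_s
  if (abs(n_per - round(n_per)) > 1e-9)
    stop("sampling_rate x block width must be an integer number of samples")
  n_per <- as.integer(round(n_per))
  n <- nrow(rec$channels)
  if (n == 0L) stop("empty recording")
  n_blocks <- n %/% n_per
  if (n_blocks == 0L) stop("recording shorter than one block")

  grp <- rep(seq_len(n_blocks), each = n_per)
  used <- seq_len(n_blocks * n_per)
  vals <- matrix(NA_real_, n_blocks, ncol(rec$channels),
                 dimnames = list(NULL, colnames(rec$channels)))
  valid <- matrix(FALSE, n_blocks, ncol(rec$channels),
                  dimnames = list(NULL, colnames(rec$channels)))
  for (j in seq_len(ncol(rec$channels))) {
    x <- rec$channels[used, j]
    fin <- is.finite(x)
    cnt <- tapply(fin, grp, sum)
    sm <- tapply(ifelse(fin, x, 0), grp, sum)
    ok <- cnt >= n_per / 2
    vals[ok, j] <- sm[ok] / cnt[ok]
    valid[, j] <- ok
  }
  structure(list(time = seq_len(n_blocks) * block_s, values = vals,
                 valid = valid, block_s = block_s, periods = rec$periods),
            class = "trend_series")
}

#' @export
print.trend_series <- function(x, ...) {
  cat(sprintf("Trend series: %d blocks of %g s, channels: %s\n",
              nrow(x$values), x$block_s,
              paste(colnames(x$values), collapse = ", ")))
  cat(sprintf("  valid fraction: %.3f\n", mean(x$valid)))
  invisible(x)
}

#' @export
plot.trend_series <- function(x, channels = colnames(x$values), ...) {
  old <- graphics::par(mfrow = c(length(channels), 1),
                       mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  for (ch in channels) {
    v <- ifelse(x$valid[, ch], x$values[, ch], NA)
    graphics::plot(x$time / 60, v, type = "l", xlab = "min", ylab = ch, ...)
  }
  invisible(x)
}

#' Reject out-of-range trend blocks and derive CPP
#'
#' Applies the automated artifact thresholds at the 10-s block level: ICP
#' blocks outside [-10, 60] mmHg are invalidated; cerebral perfusion
#' pressure is computed per block as ABP - ICP, and blocks with CPP outside
#' [0, 150] mmHg invalidate both ICP and CPP. Already-invalid blocks stay
#' invalid (the mask only shrinks). Optionally the same ICP thresholds can
#' be applied at the raw-sample level before block statistics via
#' [coarse_grain()] by pre-masking, but the block-level rule is the default.
#'
#' @param trend a \code{trend_series} containing ABP and ICP channels.
#' @param icp_range,cpp_range acceptance intervals in mmHg.
#' @return The trend with a CPP channel appended and the validity mask
#'   tightened.
#' @export
reject_artifacts <- function(trend, icp_range = c(-10, 60),
                             cpp_range = c(0, 150)) {
  stopifnot(inherits(trend, "trend_series"))
  need <- c("ABP", "ICP")
  miss <- setdiff(need, colnames(trend$values))
  if (length(miss)) stop("missing required channel(s): ",
                         paste(miss, collapse = ", "))
  icp <- trend$values[, "ICP"]
  icp_ok <- trend$valid[, "ICP"] & !is.na(icp) &
    icp >= icp_range[1] & icp <= icp_range[2]

  cpp <- trend$values[, "ABP"] - trend$values[, "ICP"]
  cpp_defined <- icp_ok & trend$valid[, "ABP"] & !is.na(cpp)
  cpp_bad <- cpp_defined & (cpp < cpp_range[1] | cpp > cpp_range[2])

  trend$valid[, "ICP"] <- icp_ok & !cpp_bad
  trend$values <- cbind(trend$values, CPP = cpp)
  trend$valid <- cbind(trend$valid, CPP = cpp_defined & !cpp_bad)
  trend
}

#' Intracranial pulse amplitude per 10-s block
#'
#' Extracts the cardiac pulsation amplitude of the ICP waveform block by
#' block. The default (\code{method = "spectral"}) takes twice the
#' magnitude of the Hann-windowed single-frequency Fourier component of the
#' block at the fundamental cardiac frequency, i.e. a peak-to-peak
#' convention: a pure sinusoid of amplitude a yields AMP = 2a. The
#' alternative \code{method = "beat"} reports the median per-beat
#' peak-to-peak excursion over the block.
#'
#' The cardiac frequency is taken from \code{f_cardiac} when supplied, else
#' detected as the largest periodogram peak of the ABP channel in the
#' 0.5--5 Hz band.
#'
#' @param rec a \code{waveform_recording} with an ICP channel (ABP needed
#'   only for detection), sampled at >= 20 Hz.
#' @param trend the \code{trend_series} from [coarse_grain()] whose block
#'   grid and validity the AMP channel joins.
#' @param f_cardiac cardiac frequency in Hz, or \code{NULL} to detect.
#' @param method \code{"spectral"} (default) or \code{"beat"}.
#' @return The trend with an AMP channel appended.
#' @export
compute_amp <- function(rec, trend, f_cardiac = NULL,
                        method = c("spectral", "beat")) {
  method <- match.arg(method)
  stopifnot(inherits(rec, "waveform_recording"),
            inherits(trend, "trend_series"))
  fs <- rec$sampling_rate
  if (fs < 20) stop("AMP extraction requires sampling_rate >= 20 Hz")
  if (is.null(f_cardiac)) f_cardiac <- detect_cardiac_frequency(rec)
  if (f_cardiac < 0.5 || f_cardiac > 5)
    stop("cardiac frequency ", signif(f_cardiac, 3),
         " Hz outside the plausible 0.5-5 Hz range")

  n_per <- as.integer(round(fs * trend$block_s))
  n_blocks <- nrow(trend$values)
  icp <- rec$channels[, "ICP"]
  amp <- rep(NA_real_, n_blocks)
  tt <- (seq_len(n_per) - 1) / fs
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n_per - 1) / (n_per - 1))  # Hann
  rot <- exp(-2i * pi * f_cardiac * tt)
  for (b in seq_len(n_blocks)) {
    x <- icp[((b - 1L) * n_per + 1L):(b * n_per)]
    if (!all(is.finite(x))) {
      fin <- is.finite(x)
      if (mean(fin) < 0.5) next
      x[!fin] <- mean(x[fin])
    }
    if (method == "spectral") {
      a <- 2 * Mod(sum(w * (x - mean(x)) * rot)) / sum(w)
      amp[b] <- 2 * a
    } else {
      amp[b] <- beat_amp(x, fs, f_cardiac)
    }
  }
  ok <- trend$valid[, "ICP"] & !is.na(amp)
  trend$values <- cbind(trend$values, AMP = amp)
  trend$valid <- cbind(trend$valid, AMP = ok)
  trend
}

detect_cardiac_frequency <- function(rec, channel = "ABP",
                                     band = c(0.5, 5)) {
  x <- rec$channels[, channel]
  n <- min(length(x), as.integer(rec$sampling_rate * 600))  # <= 10 min
  x <- x[seq_len(n)]
  x <- x - mean(x)
  sp <- Mod(stats::fft(x))^2
  f <- (seq_along(sp) - 1) * rec$sampling_rate / n
  in_band <- f >= band[1] & f <= band[2]
  if (!any(in_band)) stop("no spectral support in the cardiac band")
  f[in_band][which.max(sp[in_band])]
}

# median per-beat peak-to-peak amplitude within one block
beat_amp <- function(x, fs, f_cardiac) {
  per <- max(2L, as.integer(round(fs / f_cardiac)))
  nb <- length(x) %/% per
  if (nb < 1L) return(NA_real_)
  pp <- vapply(seq_len(nb), function(k) {
    seg <- x[((k - 1L) * per + 1L):(k * per)]
    max(seg) - min(seg)
  }, numeric(1))
  stats::median(pp)
}
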