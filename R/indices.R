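#' Minute-updated moving Pearson correlation of two trend channels
#'
#' At every minute boundary from 300 s onward, computes the Pearson
#' correlation over the trailing 5-min window of 30 consecutive 10-s block
#' averages, using only blocks valid in both channels. A window is invalid
#' if fewer than \code{min_valid} of its 30 pairs are valid or either
#' channel is constant within the window. The Fisher transform
#' \code{z = atanh(r)} is applied after clamping \code{|r|} at
#' \code{clamp} so z stays finite.
#'
#' @param trend a \code{trend_series}.
#' @param x,y channel names sharing the trend's block grid.
#' @param window number of blocks per window (default 30 = 5 min).
#' @param step update interval in blocks (default 6 = 1 min).
#' @param min_valid minimum valid pairs per window (default 24).
#' @param clamp clamp on |r| before the Fisher transform (default 0.99).
#' @return An \code{index_series} data frame: \code{time} (window end, s),
#'   \code{r}, \code{z}, \code{window_n} (valid pairs), \code{valid}.
#' @export
moving_correlation <- function(trend, x, y, window = 30L, step = 6L,
                               min_valid = 24L, clamp = 0.99) {
  stopifnot(inherits(trend, "trend_series"))
  for (ch in c(x, y))
    if (!ch %in% colnames(trend$values)) stop("no such channel: ", ch)
  xv <- trend$values[, x]; yv <- trend$values[, y]
  ok <- trend$valid[, x] & trend$valid[, y] &
    is.finite(xv) & is.finite(yv)
  nb <- nrow(trend$values)
  ends <- seq(window, nb, by = step)
  out <- data.frame(time = trend$time[ends], r = NA_real_, z = NA_real_,
                    window_n = 0L, valid = FALSE)
  for (k in seq_along(ends)) {
    idx <- (ends[k] - window + 1L):ends[k]
    use <- idx[ok[idx]]
    out$window_n[k] <- length(use)
    if (length(use) < min_valid) next
    sx <- stats::sd(xv[use]); sy <- stats::sd(yv[use])
    if (sx == 0 || sy == 0) next
    r <- stats::cor(xv[use], yv[use])
    out$r[k] <- r
    out$z[k] <- atanh(pmin(pmax(r, -clamp), clamp))
    out$valid[k] <- TRUE
  }
  class(out) <- c("index_series", "data.frame")
  out
}

#' Pressure reactivity index (PRx)
#'
#' Moving correlation between 30 consecutive 10-s averages of arterial and
#' intracranial pressure, updated every minute. Negative values indicate
#' preserved cerebrovascular reactivity; positive values impairment.
#'
#' @inheritParams moving_correlation
#' @param ... passed to [moving_correlation()].
#' @return An \code{index_series}.
#' @export
compute_prx <- function(trend, ...) {
  moving_correlation(trend, "ABP", "ICP", ...)
}

#' Compensatory reserve index (RAP)
#'
#' Moving correlation between 30 consecutive 10-s averages of intracranial
#' pulse amplitude (AMP) and mean ICP, updated every minute. Values near 0
#' indicate preserved compensatory reserve; values approaching 1 indicate
#' exhausted intracranial compliance.
#'
#' @inheritParams moving_correlation
#' @param ... passed to [moving_correlation()].
#' @return An \code{index_series}.
#' @export
compute_rap <- function(trend, ...) {
  if (!"AMP" %in% colnames(trend$values))
    stop("trend has no AMP channel; run compute_amp() first")
  moving_correlation(trend, "AMP", "ICP", ...)
}

#' @export
print.index_series <- function(x, ...) {
  cat(sprintf("Index series: %d updates, %d valid; mean r = %.3f\n",
              nrow(x), sum(x$valid), mean(x$r[x$valid])))
  invisible(x)
}

#' @export
plot.index_series <- function(x, ...) {
  graphics::plot(x$time / 60, x$r, type = "l", ylim = c(-1, 1),
                 xlab = "min", ylab = "r", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
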