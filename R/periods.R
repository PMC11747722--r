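#' Per-period summary of trends and indices
#'
#' Averages every trend channel and the correlation indices within each
#' annotated protocol period. Only valid blocks/windows are used. PRx and
#' RAP are averaged on the Fisher-z scale; both the mean z and the
#' back-transformed \code{tanh(mean z)} are reported. Change-from-baseline
#' columns (\code{delta_icp}, \code{delta_prx}, \code{delta_prx_z}) are
#' computed against the PEEP-baseline period of the same position block.
#'
#' @param trend a \code{trend_series} (after [reject_artifacts()] and
#'   [compute_amp()]).
#' @param prx,rap \code{index_series} from [compute_prx()] /
#'   [compute_rap()] (\code{rap} may be \code{NULL}).
#' @param design data frame of period rows (columns \code{animal},
#'   \code{sequence}, \code{block}, \code{position}, \code{period_index},
#'   \code{peep}, \code{period_label}, \code{start}, \code{end}).
#' @return A data frame with one row per period; rows with no valid ICP
#'   block are flagged \code{valid = FALSE}.
#' @export
summarize_periods <- function(trend, prx, rap = NULL, design) {
  stopifnot(inherits(trend, "trend_series"))
  if (any(design$end - design$start < 300))
    stop("periods must be at least 300 s long")
  chans <- colnames(trend$values)
  rows <- vector("list", nrow(design))
  for (k in seq_len(nrow(design))) {
    d <- design[k, ]
    in_p <- trend$time > d$start & trend$time <= d$end
    row <- d[c("animal", "sequence", "block", "position", "period_index",
               "peep", "period_label")]
    for (ch in chans) {
      use <- in_p & trend$valid[, ch]
      row[[tolower(ch)]] <- if (any(use)) mean(trend$values[use, ch]) else NA_real_
    }
    row$n_valid_icp <- sum(in_p & trend$valid[, "ICP"])
    row$valid <- row$n_valid_icp > 0L
    row <- cbind(row, index_period_mean(prx, d, "prx"))
    if (!is.null(rap)) row <- cbind(row, index_period_mean(rap, d, "rap"))
    rows[[k]] <- row
  }
  out <- do.call(rbind, rows)
  add_baseline_deltas(out)
}

index_period_mean <- function(ix, d, name) {
  use <- ix$valid & ix$time > d$start & ix$time <= d$end
  z <- if (any(use)) mean(ix$z[use]) else NA_real_
  res <- data.frame(a = tanh(z), b = z)
  names(res) <- c(name, paste0(name, "_z"))
  res
}

add_baseline_deltas <- function(tbl) {
  tbl$delta_icp <- NA_real_
  tbl$delta_prx <- NA_real_
  tbl$delta_prx_z <- NA_real_
  key <- interaction(tbl$animal, tbl$block, drop = TRUE)
  for (k in levels(key)) {
    i <- which(key == k)
    b <- i[tbl$period_label[i] == "baseline"]
    if (length(b) != 1L) next
    tbl$delta_icp[i] <- tbl$icp[i] - tbl$icp[b]
    if ("prx" %in% names(tbl)) {
      tbl$delta_prx[i] <- tbl$prx[i] - tbl$prx[b]
      tbl$delta_prx_z[i] <- tbl$prx_z[i] - tbl$prx_z[b]
    }
  }
  tbl
}

#' Run the full trend pipeline on one recording
#'
#' Chains coarse-graining, block-level artifact rejection (with CPP
#' derivation), pulse-amplitude extraction, PRx and RAP, and, when period
#' annotations are available, the per-period summary.
#'
#' @param rec a \code{waveform_recording}.
#' @param design period annotations; defaults to \code{rec$periods}.
#' @param f_cardiac cardiac frequency in Hz, or NULL to detect from ABP.
#' @param amp_method \code{"spectral"} or \code{"beat"}; see
#'   [compute_amp()].
#' @param artifact_level \code{"block"} (default) applies the rejection
#'   thresholds to 10-s block values; \code{"raw"} additionally masks raw
#'   ICP samples outside the ICP range before block averaging.
#' @param icp_range,cpp_range rejection thresholds in mmHg.
#' @param ... passed to [moving_correlation()].
#' @return A list with \code{trend}, \code{prx}, \code{rap} and
#'   \code{summary} (NULL without annotations).
#' @export
process_recording <- function(rec, design = rec$periods, f_cardiac = NULL,
                              amp_method = "spectral",
                              artifact_level = c("block", "raw"),
                              icp_range = c(-10, 60), cpp_range = c(0, 150),
                              ...) {
  artifact_level <- match.arg(artifact_level)
  if (artifact_level == "raw") {
    bad <- rec$channels[, "ICP"] < icp_range[1] |
      rec$channels[, "ICP"] > icp_range[2]
    rec$channels[bad, "ICP"] <- NA_real_
  }
  trend <- coarse_grain(rec)
  trend <- reject_artifacts(trend, icp_range, cpp_range)
  trend <- compute_amp(rec, trend, f_cardiac = f_cardiac,
                       method = amp_method)
  prx <- compute_prx(trend, ...)
  rap <- compute_rap(trend, ...)
  summary <- if (!is.null(design))
    summarize_periods(trend, prx, rap, design) else NULL
  list(trend = trend, prx = prx, rap = rap, summary = summary)
}
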