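#' Read and write waveform recordings as CSV
#'
#' The on-disk dialect is a plain UTF-8 comma-separated file with a header
#' row, a leading \code{time} column in elapsed seconds from recording
#' start, and one column per channel (dot decimal separator). Time must be
#' strictly increasing and uniformly sampled (relative jitter below 1e-6);
#' the sampling rate is recovered from the median time step.
#'
#' @param path file path.
#' @return [read_waveforms()] returns a \code{waveform_recording};
#'   [write_waveforms()] returns the path invisibly. Round-trips are
#'   lossless to full double precision.
#' @export
read_waveforms <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df))
    stop("waveform CSV must have a leading 'time' column: ", path)
  t <- df$time
  if (any(diff(t) <= 0)) stop("non-monotonic time column in ", path)
  dt <- diff(t)
  dt0 <- stats::median(dt)
  if (any(abs(dt - dt0) > 1e-6 * dt0))
    stop("inconsistent sampling interval (relative jitter > 1e-6) in ", path)
  chan <- as.matrix(df[setdiff(names(df), "time")])
  new_waveform_recording(chan, sampling_rate = 1 / dt0, start_time = t[1])
}

#' @param rec a \code{waveform_recording}.
#' @rdname read_waveforms
#' @export
write_waveforms <- function(rec, path) {
  stopifnot(inherits(rec, "waveform_recording"))
  n <- nrow(rec$channels)
  df <- data.frame(time = rec$start_time + (seq_len(n) - 1) / rec$sampling_rate)
  df <- cbind(df, as.data.frame(rec$channels))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write and read 0.1 Hz trend series as CSV
#'
#' One row per 10-s block: \code{time}, a value column per channel, and a
#' \code{<channel>_valid} flag column per channel.
#'
#' @param trend a \code{trend_series}.
#' @param path file path.
#' @return [write_trends()] the path, invisibly; [read_trends()] a
#'   \code{trend_series}.
#' @export
write_trends <- function(trend, path) {
  stopifnot(inherits(trend, "trend_series"))
  df <- data.frame(time = trend$time)
  for (ch in colnames(trend$values)) {
    df[[ch]] <- trend$values[, ch]
    df[[paste0(ch, "_valid")]] <- trend$valid[, ch]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trends
#' @export
read_trends <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  chans <- setdiff(names(df)[!grepl("_valid$", names(df))], "time")
  vals <- as.matrix(df[chans])
  valid <- as.matrix(df[paste0(chans, "_valid")])
  colnames(valid) <- chans
  block_s <- if (nrow(df) > 1) df$time[2] - df$time[1] else 10
  structure(list(time = df$time, values = vals,
                 valid = matrix(as.logical(valid), nrow(valid),
                                dimnames = dimnames(valid)),
                 block_s = block_s, periods = NULL),
            class = "trend_series")
}

#' Read a study design table
#'
#' Validates a design CSV (columns \code{animal}, \code{sequence},
#' \code{block}, \code{position}, \code{period_index}, \code{peep},
#' \code{period_label}, \code{start}, \code{end}; times in elapsed
#' seconds, half-open \code{[start, end)} intervals). Periods of the same
#' animal must not overlap; violations are reported with the offending row
#' numbers.
#'
#' @param path file path.
#' @return The validated design data frame.
#' @export
read_design <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal", "sequence", "block", "position", "period_index",
            "peep", "period_label", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("design CSV missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$end <= df$start))
    stop("design rows with end <= start: ",
         paste(which(df$end <= df$start), collapse = ", "))
  for (a in unique(df$animal)) {
    i <- which(df$animal == a)
    o <- i[order(df$start[i])]
    bad <- o[-1][df$start[o][-1] < df$end[o][-length(o)]]
    if (length(bad))
      stop("overlapping periods for animal ", a, " at row(s): ",
           paste(bad, collapse = ", "))
  }
  df
}

#' Run the full simulate-process-mechanics-stats pipeline
#'
#' End-to-end driver: simulates a study from a [synth_config()], runs the
#' trend pipeline on every recording, derives respiratory mechanics from
#' the hold table, assembles the study table, and runs the crossover
#' statistical analysis. When \code{out_dir} is given, writes the study
#' table, ground truth, statistical reports and a JSON run manifest
#' (seed, configuration hash, package version) so a run is reproducible
#' from its outputs.
#'
#' @param config a [synth_config()].
#' @param out_dir output directory, or \code{NULL} to skip writing.
#' @param amp_method,artifact_level passed to [process_recording()].
#' @return A list with \code{study_table}, \code{ground_truth},
#'   \code{assumptions}, \code{anova2}, \code{rm_anova}, \code{baselines},
#'   \code{screen} and \code{manifest}.
#' @export
run_pipeline <- function(config, out_dir = NULL, amp_method = "spectral",
                         artifact_level = "block") {
  study <- simulate_study(config)
  summaries <- vector("list", length(study$recordings))
  for (i in seq_along(study$recordings)) {
    res <- process_recording(study$recordings[[i]],
                             f_cardiac = config$heart_rate / 60,
                             amp_method = amp_method,
                             artifact_level = artifact_level)
    summaries[[i]] <- res$summary
  }
  per <- do.call(rbind, summaries)
  mech <- compute_mechanics(study$holds)
  key <- c("animal", "block", "period_index")
  tbl <- merge(per, mech[setdiff(names(mech),
                                 c("position", "peep", "period_label"))],
               by = key, sort = FALSE)
  tbl <- tbl[order(tbl$animal, tbl$block, tbl$period_index), ]

  assumptions <- test_crossover_assumptions(tbl, "delta_icp")
  anova2 <- anova_peep_position(tbl, "delta_icp")
  rm_anova <- pooled_change_anova(tbl, "delta_icp")
  baselines <- tryCatch(compare_baselines(tbl), error = function(e) {
    warning("baseline comparison skipped: ", conditionMessage(e))
    NULL
  })
  screen <- baseline_correlation_screen(tbl)

  manifest <- list(
    package = "lungbrain",
    version = as.character(utils::packageVersion("lungbrain")),
    seed = config$seed,
    n_animals = config$n_animals,
    config_hash = config_hash(config),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  out <- list(study_table = tbl, ground_truth = study$ground_truth,
              assumptions = assumptions, anova2 = anova2,
              rm_anova = rm_anova, baselines = baselines, screen = screen,
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tbl, file.path(out_dir, "study_table.csv"),
                     row.names = FALSE)
    utils::write.csv(study$ground_truth,
                     file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
    if (!is.null(baselines))
      utils::write.csv(baselines,
                       file.path(out_dir, "baseline_comparison.csv"),
                       row.names = FALSE)
    utils::write.csv(screen, file.path(out_dir, "covariate_screen.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(manifest = manifest,
           p_values = list(assumptions = assumptions$p, anova2 = anova2$p,
                           rm_anova = rm_anova$p)),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

# stable content hash of the configuration (md5 of its canonical JSON)
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
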