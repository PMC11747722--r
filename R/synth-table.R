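#' Simulate a study summary table directly (no waveforms)
#'
#' Generates the per-period study table at the summary level with the same
#' effect structure as the waveform generator — animal-specific baselines
#' and covariates, PEEP slope modified by centered covariates, a supine
#' position offset, optional sequence/period/carry-over effects — but
#' drawing period means directly instead of synthesizing and re-processing
#' waveforms. Period-level residual noise stands in for within-period
#' averaging error. This is the fast path for power and type-I-error
#' simulations of the statistics stage; the full waveform path remains the
#' reference for the signal-processing stages.
#'
#' @param config a [synth_config()] object (effects and distributions are
#'   read from it).
#' @param resid_sd period-level residual SD of the ICP mean (mmHg).
#' @param prx_resid_sd period-level residual SD of PRx on the Fisher-z
#'   scale.
#' @param sequence_effect additive outcome shift (mmHg) for supine-first
#'   animals, for violation injection (default 0).
#' @param period_effect additive shift in the second position block
#'   (default 0).
#' @param carryover_effect additive shift on intervention periods of the
#'   second block (carried over from the first block's treatment, default
#'   0).
#' @return A study table: one row per animal x period with \code{icp},
#'   \code{prx}, \code{prx_z}, covariate columns, mechanics-ready hold
#'   columns, and change-from-baseline deltas.
#' @export
simulate_study_table <- function(config, resid_sd = 0.5,
                                 prx_resid_sd = 0.15,
                                 sequence_effect = 0, period_effect = 0,
                                 carryover_effect = 0) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  tabs <- lapply(seq_len(config$n_animals), function(i) {
    set.seed(animal_seed(config$seed, i))
    truth <- draw_animal_truth(config, i)
    design <- build_animal_design(config, truth)
    holds <- generate_holds(config, truth, design)

    supine <- as.numeric(design$position == "supine")
    second <- as.numeric(design$block == 2L)
    interv <- as.numeric(design$period_label == "intervention")
    sf <- as.numeric(truth$sequence == "supine-first")
    icp <- truth$baseline_icp +
      truth$position_offset * supine +
      truth$icp_peep_slope * (design$peep - config$peep_sequence[1]) / 5 +
      sequence_effect * sf + period_effect * second +
      carryover_effect * second * interv +
      stats::rnorm(nrow(design), 0, resid_sd)
    prx_z <- atanh(pmin(pmax(config$coupling_g, -0.99), 0.99)) +
      stats::rnorm(nrow(design), 0, prx_resid_sd)
    amp <- config$amp_a0 +
      config$amp_a1 * pmax(icp - config$amp_threshold, 0)
    rap_z <- atanh(pmin(pmax(
      ifelse(icp > config$amp_threshold, 0.8, 0.1) +
        stats::rnorm(nrow(design), 0, 0.1), -0.99), 0.99))

    tab <- cbind(design[c("animal", "sequence", "block", "position",
                          "period_index", "peep", "period_label")],
                 data.frame(icp = icp, abp = config$abp_mean,
                            cpp = config$abp_mean - icp,
                            cvp = truth$cvp +
                              0.5 * (design$peep - config$peep_sequence[1]) / 5,
                            amp = amp,
                            prx = tanh(prx_z), prx_z = prx_z,
                            rap = tanh(rap_z), rap_z = rap_z,
                            n_valid_icp = NA_integer_, valid = TRUE))
    hold_cols <- setdiff(names(holds),
                         c("animal", "block", "position", "period_index",
                           "peep", "period_label"))
    tab <- cbind(tab, holds[hold_cols])
    add_baseline_deltas(tab)
  })
  out <- do.call(rbind, tabs)
  compute_mechanics(out)
}
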