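#' Configuration for the synthetic physiology generator
#'
#' Builds the parameter set that defines a simulated crossover study: a group
#' of mechanically ventilated animals, each recorded through two position
#' blocks (prone and supine, order randomized) of a stepwise PEEP protocol
#' (default 5, 10, 15, 20, back to 5 cmH2O, 20 min per level) separated by a
#' washout period at baseline settings.
#'
#' The generator's physiological structure mirrors what trend-based
#' cerebrovascular monitoring assumes: arterial pressure carries slow
#' vasogenic oscillations in the 0.005--0.05 Hz band plus respiratory and
#' cardiac components; intracranial pressure is a baseline (animal-specific,
#' plus a position offset and a PEEP-proportional shift) to which the
#' standardized slow arterial component is added with a tunable coupling
#' coefficient \code{coupling_g}. The coupling is constructed so that the
#' expected pressure reactivity index equals \code{coupling_g}: the slow ICP
#' component is \code{g * zA + sqrt(1 - g^2) * zB} with \code{zA} the
#' standardized slow ABP component and \code{zB} an independent slow process.
#' Negative \code{coupling_g} therefore models intact autoregulation,
#' positive values impaired reactivity.
#'
#' The intracranial pulse amplitude follows a compensatory-reserve model:
#' \code{AMP = amp_a0 + amp_a1 * max(mean ICP - amp_threshold, 0)}, flat
#' below the threshold (RAP near 0) and rising linearly with ICP above it
#' (RAP approaching 1).
#'
#' Each animal's PEEP response slope is
#' \code{icp_peep_slope + sum(covariate_effects * centered covariates) +
#' N(0, icp_peep_slope_sd)}, so that baseline covariates (baseline ICP, CVP,
#' respiratory-system elastance, transpulmonary pressures) modulate the ICP
#' response with configurable signs, providing ground truth for the
#' exploratory correlation screen.
#'
#' @param n_animals number of animals in the study (default 12).
#' @param weight_kg body mass in kg: a scalar for identical animals or a
#'   \code{c(min, max)} range for per-animal uniform draws; tidal volume is
#'   \code{vt_ml_per_kg * weight_kg} mL.
#' @param sampling_rate waveform sampling rate in Hz; must be at least 20
#'   times the cardiac frequency.
#' @param heart_rate beats per minute.
#' @param resp_rate breaths per minute (ventilated, volume control): a
#'   scalar, or a \code{c(min, max)} range drawn per animal (protocol
#'   20--30).
#' @param peep_sequence ordered PEEP levels in cmH2O applied in each position
#'   block.
#' @param period_minutes duration of each PEEP period in minutes; must
#'   exceed 5 so every period holds at least one full correlation window.
#' @param washout_minutes duration of the between-block washout at baseline
#'   settings.
#' @param coupling_g cerebrovascular reactivity coefficient in [-1, 1];
#'   expected PRx in the noise-free limit.
#' @param icp_peep_slope population mean ICP rise in mmHg per 5 cmH2O of
#'   PEEP above baseline.
#' @param icp_peep_slope_sd between-animal SD of the PEEP slope (mmHg per
#'   5 cmH2O).
#' @param position_offset_mmHg ICP offset added in the supine position
#'   (mmHg); supine reads higher than prone in pigs because the frontal
#'   probe sits lower.
#' @param covariate_effects named numeric vector of slope modifiers (mmHg
#'   per 5 cmH2O per unit of centered covariate) for
#'   \code{icp}, \code{cvp}, \code{e_rs}, \code{tpp_ei}, \code{tpp_ee}.
#' @param baseline_icp_mean,baseline_icp_sd population distribution of
#'   prone baseline ICP (mmHg).
#' @param cvp_mean,cvp_sd central venous pressure distribution (mmHg).
#' @param e_cw_mean,e_cw_sd,e_l_mean,e_l_sd chest-wall and lung elastance
#'   distributions (cmH2O/L); E_rs = E_cw + E_l per animal.
#' @param pes_ee_mean,pes_ee_sd end-expiratory esophageal pressure at
#'   baseline PEEP (cmH2O).
#' @param abp_mean mean arterial pressure (mmHg).
#' @param abp_slow_sd SD of the slow (0.005--0.05 Hz) ABP component (mmHg).
#' @param abp_pulse_amp cardiac pulse amplitude of ABP (mmHg, half
#'   peak-to-peak).
#' @param abp_resp_amp respiratory modulation amplitude of ABP (mmHg).
#' @param icp_slow_sd SD of the slow ICP component (mmHg).
#' @param icp_resp_amp respiratory modulation amplitude of ICP (mmHg).
#' @param amp_a0,amp_a1,amp_threshold pulse-amplitude model: intercept
#'   (mmHg), slope per mmHg of ICP above threshold, and threshold (mmHg).
#' @param n_slow_components sinusoids per slow process, frequencies drawn
#'   uniformly from the slow band.
#' @param slow_band two-element frequency band (Hz) of the slow waves.
#' @param vt_ml_per_kg tidal volume in mL per kg (protocol 7--8).
#' @param airway_resistance airway resistance in cmH2O/(L/s), used for peak
#'   (dynamic) pressures.
#' @param noise_sd named per-channel additive white-noise SD, and the SD
#'   applied to hold-measurement pressures; set to 0 for noise-free
#'   identities.
#' @param seed integer seed; with \code{animal} index it fully determines
#'   every recording.
#'
#' @return An object of class \code{synth_config} (a validated list).
#' @seealso [simulate_animal()], [simulate_study()], [simulate_study_table()]
#' @export
synth_config <- function(n_animals = 12L,
                         weight_kg = c(23, 28),
                         sampling_rate = 50,
                         heart_rate = 100,
                         resp_rate = c(20, 30),
                         peep_sequence = c(5, 10, 15, 20, 5),
                         period_minutes = 20,
                         washout_minutes = 20,
                         coupling_g = -0.3,
                         icp_peep_slope = 1.0,
                         icp_peep_slope_sd = 0.4,
                         position_offset_mmHg = 5,
                         covariate_effects = c(icp = 0.08, cvp = 0.15,
                                               e_rs = -0.02, tpp_ei = -0.08,
                                               tpp_ee = -0.05),
                         baseline_icp_mean = 7, baseline_icp_sd = 3,
                         cvp_mean = 12, cvp_sd = 2,
                         e_cw_mean = 19, e_cw_sd = 4,
                         e_l_mean = 33, e_l_sd = 6,
                         pes_ee_mean = 4, pes_ee_sd = 1.5,
                         abp_mean = 85, abp_slow_sd = 3,
                         abp_pulse_amp = 15, abp_resp_amp = 2,
                         icp_slow_sd = 1.5, icp_resp_amp = 0.8,
                         amp_a0 = 1, amp_a1 = 0.15, amp_threshold = 15,
                         n_slow_components = 6L,
                         slow_band = c(0.005, 0.05),
                         vt_ml_per_kg = 7.5,
                         airway_resistance = 10,
                         noise_sd = c(ABP = 0.5, ICP = 0.3, CVP = 0.3,
                                      Paw = 0.2, Pes = 0.2, Flow = 0.02,
                                      Volume = 0.005, hold = 0.2),
                         seed = 1L) {
  cfg <- list(
    n_animals = as.integer(n_animals), weight_kg = weight_kg,
    sampling_rate = sampling_rate, heart_rate = heart_rate,
    resp_rate = resp_rate, peep_sequence = peep_sequence,
    period_minutes = period_minutes, washout_minutes = washout_minutes,
    coupling_g = coupling_g, icp_peep_slope = icp_peep_slope,
    icp_peep_slope_sd = icp_peep_slope_sd,
    position_offset_mmHg = position_offset_mmHg,
    covariate_effects = covariate_effects,
    baseline_icp_mean = baseline_icp_mean, baseline_icp_sd = baseline_icp_sd,
    cvp_mean = cvp_mean, cvp_sd = cvp_sd,
    e_cw_mean = e_cw_mean, e_cw_sd = e_cw_sd,
    e_l_mean = e_l_mean, e_l_sd = e_l_sd,
    pes_ee_mean = pes_ee_mean, pes_ee_sd = pes_ee_sd,
    abp_mean = abp_mean, abp_slow_sd = abp_slow_sd,
    abp_pulse_amp = abp_pulse_amp, abp_resp_amp = abp_resp_amp,
    icp_slow_sd = icp_slow_sd, icp_resp_amp = icp_resp_amp,
    amp_a0 = amp_a0, amp_a1 = amp_a1, amp_threshold = amp_threshold,
    n_slow_components = as.integer(n_slow_components),
    slow_band = slow_band,
    vt_ml_per_kg = vt_ml_per_kg, airway_resistance = airway_resistance,
    noise_sd = noise_sd, seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(cfg$n_animals >= 1L)
  if (cfg$period_minutes <= 5)
    stop("period_minutes must exceed 5 (>= one full correlation window per period)")
  if (cfg$washout_minutes <= 0 || cfg$sampling_rate <= 0 ||
      cfg$heart_rate <= 0 || any(cfg$resp_rate <= 0) ||
      any(cfg$weight_kg <= 0))
    stop("durations and rates must be positive")
  f_card <- cfg$heart_rate / 60
  if (cfg$sampling_rate < 20 * f_card)
    stop("sampling_rate must be at least 20 x cardiac frequency (",
         20 * f_card, " Hz)")
  if (abs(cfg$coupling_g) > 1)
    stop("|coupling_g| must not exceed 1")
  if (cfg$e_cw_mean <= 0 || cfg$e_l_mean <= 0)
    stop("elastances must be positive")
  if (length(cfg$slow_band) != 2L || cfg$slow_band[1] <= 0 ||
      cfg$slow_band[2] <= cfg$slow_band[1])
    stop("slow_band must be an increasing positive pair of frequencies")
  needed <- c("ABP", "ICP", "CVP", "Paw", "Pes", "Flow", "Volume", "hold")
  miss <- setdiff(needed, names(cfg$noise_sd))
  if (length(miss))
    stop("noise_sd must name: ", paste(miss, collapse = ", "))
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic crossover-study configuration\n")
  cat(sprintf("  %d animals, %s kg, seed %d\n", x$n_animals,
              paste(x$weight_kg, collapse = "-"), x$seed))
  cat(sprintf("  PEEP sequence %s cmH2O, %g min per period, %g min washout\n",
              paste(x$peep_sequence, collapse = "/"), x$period_minutes,
              x$washout_minutes))
  cat(sprintf("  coupling_g = %g, ICP slope %g mmHg per 5 cmH2O (SD %g)\n",
              x$coupling_g, x$icp_peep_slope, x$icp_peep_slope_sd))
  cat(sprintf("  waveforms at %g Hz, HR %g /min, RR %s /min\n",
              x$sampling_rate, x$heart_rate,
              paste(x$resp_rate, collapse = "-")))
  invisible(x)
}
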