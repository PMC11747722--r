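#' Simulate one animal's full crossover recording
#'
#' Generates a multichannel waveform recording spanning both position blocks
#' of the PEEP protocol (each block: the configured PEEP sequence, default
#' 5/10/15/20/5 cmH2O at 20 min per level) separated by a washout period at
#' baseline settings, together with the animal's ground-truth parameters.
#'
#' Channels: ABP, ICP, CVP (mmHg), Paw, Pes (cmH2O), Flow (L/s), Volume (L).
#' ABP is mean pressure plus a slow vasogenic component (sum of sinusoids in
#' the configured 0.005--0.05 Hz band), respiratory modulation, and a cardiac
#' pulse. ICP is the animal baseline, plus a supine position offset, plus the
#' PEEP effect (animal-specific slope times PEEP elevation above baseline),
#' plus the coupled slow component \code{g * zA + sqrt(1-g^2) * zB} scaled by
#' \code{icp_slow_sd}, plus a cardiac pulse whose amplitude grows linearly
#' with mean ICP above the compensatory-reserve threshold. Ventilator
#' waveforms follow a single-compartment model with the animal's true
#' elastances, so occlusion holds recover them exactly when noise is off.
#'
#' The result is bit-reproducible for a fixed \code{(seed, animal)} pair.
#'
#' @param config a [synth_config()] object.
#' @param animal 1-based animal index, at most \code{config$n_animals}.
#' @return A list with elements \code{recording} (a
#'   \code{waveform_recording}: \code{channels} matrix, \code{sampling_rate},
#'   \code{start_time}, \code{periods}, \code{artifacts}), \code{truth}
#'   (one-row data frame of true parameters), \code{design} (per-period
#'   rows), and \code{holds} (per-period occlusion-hold measurements).
#' @export
simulate_animal <- function(config, animal) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  animal <- as.integer(animal)
  if (animal < 1L || animal > config$n_animals)
    stop("animal index out of range 1..", config$n_animals)

  set.seed(animal_seed(config$seed, animal))
  truth <- draw_animal_truth(config, animal)
  design <- build_animal_design(config, truth)
  holds <- generate_holds(config, truth, design)

  fs <- config$sampling_rate
  total_s <- max(design$end)
  n <- round(total_s * fs)
  t <- (seq_len(n) - 1) / fs

  # per-sample protocol state
  idx <- findInterval(t, design$start)       # periods are contiguous
  peep <- design$peep[idx]
  supine <- as.numeric(design$position[idx] == "supine")

  # slow vasogenic processes, standardized over the recording
  zA <- standardize(slow_process(t, config))
  zB <- standardize(slow_process(t, config))
  g <- config$coupling_g

  f_c <- config$heart_rate / 60
  f_r <- truth$rr / 60
  ph <- stats::runif(4, 0, 2 * pi)

  abp <- config$abp_mean + config$abp_slow_sd * zA +
    config$abp_resp_amp * sin(2 * pi * f_r * t + ph[1]) +
    config$abp_pulse_amp * sin(2 * pi * f_c * t + ph[2])

  icp_mean <- truth$baseline_icp + config$position_offset_mmHg * supine +
    truth$icp_peep_slope * (peep - config$peep_sequence[1]) / 5 +
    config$icp_slow_sd * (g * zA + sqrt(max(0, 1 - g^2)) * zB)
  amp_t <- config$amp_a0 +
    config$amp_a1 * pmax(icp_mean - config$amp_threshold, 0)
  icp <- icp_mean + config$icp_resp_amp * sin(2 * pi * f_r * t + ph[3]) +
    (amp_t / 2) * sin(2 * pi * f_c * t + ph[4])

  cvp <- truth$cvp + 0.5 * (peep - config$peep_sequence[1]) / 5 +
    0.8 * sin(2 * pi * f_r * t + ph[3])

  vent <- ventilator_waveforms(t, peep, truth, config)

  ns <- config$noise_sd
  chan <- cbind(
    ABP = abp + noise(n, ns["ABP"]),
    ICP = icp + noise(n, ns["ICP"]),
    CVP = cvp + noise(n, ns["CVP"]),
    Paw = vent$paw + noise(n, ns["Paw"]),
    Pes = vent$pes + noise(n, ns["Pes"]),
    Flow = vent$flow + noise(n, ns["Flow"]),
    Volume = vent$volume + noise(n, ns["Volume"])
  )

  rec <- new_waveform_recording(chan, fs, periods = design)
  list(recording = rec, truth = truth, design = design, holds = holds)
}

#' Simulate a full crossover study
#'
#' Runs [simulate_animal()] for every animal and assembles the study-level
#' tables: the design skeleton (one row per animal x period), ground truth
#' (one row per animal, including the randomized position sequence), and the
#' per-period occlusion-hold measurements used by the respiratory-mechanics
#' stage. Sequence assignment is a seeded lot draw per animal with no
#' balancing constraint.
#'
#' @param config a [synth_config()] object with \code{n_animals >= 2}.
#' @return A list with \code{recordings} (list of
#'   \code{waveform_recording}), \code{ground_truth}, \code{design} and
#'   \code{holds} data frames.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_animals < 2L) stop("a study needs at least 2 animals")
  sims <- lapply(seq_len(config$n_animals),
                 function(i) simulate_animal(config, i))
  list(
    recordings = lapply(sims, `[[`, "recording"),
    ground_truth = do.call(rbind, lapply(sims, `[[`, "truth")),
    design = do.call(rbind, lapply(sims, `[[`, "design")),
    holds = do.call(rbind, lapply(sims, `[[`, "holds"))
  )
}

#' Inject labelled artifacts into a recording
#'
#' Returns a modified copy of the recording with spikes, dropouts or
#' flatlines written into stated channels over stated intervals, and the
#' exact injected intervals appended to the recording's artifact
#' annotations, so that downstream artifact-rejection masks can be checked
#' against ground truth.
#'
#' @param rec a \code{waveform_recording}.
#' @param artifacts data frame with columns \code{channel}, \code{start},
#'   \code{end} (seconds from recording start, half-open interval),
#'   \code{type} (\code{"spike"}, \code{"dropout"} or \code{"flatline"}),
#'   and \code{value} (target value for spike/dropout; ignored for
#'   flatline, which holds the sample at \code{start}).
#' @return A \code{waveform_recording} with modified channels and annotated
#'   artifact intervals. Zero-row \code{artifacts} returns the input
#'   unchanged.
#' @export
inject_artifacts <- function(rec, artifacts) {
  stopifnot(inherits(rec, "waveform_recording"))
  need <- c("channel", "start", "end", "type")
  if (!all(need %in% names(artifacts)))
    stop("artifacts must have columns: ", paste(need, collapse = ", "))
  if (nrow(artifacts) == 0L) return(rec)
  fs <- rec$sampling_rate
  dur <- nrow(rec$channels) / fs
  for (k in seq_len(nrow(artifacts))) {
    a <- artifacts[k, ]
    if (a$start < 0 || a$end > dur || a$end <= a$start)
      stop("artifact interval [", a$start, ", ", a$end,
           ") outside recording span [0, ", dur, ")")
    if (!a$channel %in% colnames(rec$channels))
      stop("no such channel: ", a$channel)
    i0 <- floor(a$start * fs) + 1L
    i1 <- ceiling(a$end * fs)
    idx <- i0:min(i1, nrow(rec$channels))
    rec$channels[idx, a$channel] <- switch(
      as.character(a$type),
      spike = ,
      dropout = a$value,
      flatline = rec$channels[i0, a$channel],
      stop("unknown artifact type: ", a$type)
    )
  }
  rec$artifacts <- rbind(rec$artifacts,
                         artifacts[, c("channel", "start", "end", "type")])
  rec
}

# ---- internals --------------------------------------------------------------

animal_seed <- function(seed, animal) {
  (as.integer(seed) + 7919L * as.integer(animal)) %% 2147483629L
}

noise <- function(n, sd) {
  if (is.na(sd) || sd <= 0) 0 else stats::rnorm(n, 0, sd)
}

standardize <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(x * 0)
  (x - mean(x)) / s
}

slow_process <- function(t, config) {
  k <- config$n_slow_components
  f <- stats::runif(k, config$slow_band[1], config$slow_band[2])
  ph <- stats::runif(k, 0, 2 * pi)
  x <- 0
  for (j in seq_len(k)) x <- x + sin(2 * pi * f[j] * t + ph[j])
  x
}

draw_range <- function(x, integer = FALSE) {
  v <- if (length(x) == 2L) stats::runif(1, x[1], x[2]) else x[1]
  if (integer) round(v) else v
}

draw_animal_truth <- function(config, animal) {
  sequence <- if (stats::runif(1) < 0.5) "prone-first" else "supine-first"
  weight <- draw_range(config$weight_kg)
  rr <- draw_range(config$resp_rate, integer = TRUE)
  baseline_icp <- stats::rnorm(1, config$baseline_icp_mean,
                               config$baseline_icp_sd)
  cvp <- stats::rnorm(1, config$cvp_mean, config$cvp_sd)
  e_cw <- max(2, stats::rnorm(1, config$e_cw_mean, config$e_cw_sd))
  e_l <- max(5, stats::rnorm(1, config$e_l_mean, config$e_l_sd))
  e_rs <- e_cw + e_l
  pes_ee0 <- stats::rnorm(1, config$pes_ee_mean, config$pes_ee_sd)
  vt_l <- config$vt_ml_per_kg * weight / 1000
  peep0 <- config$peep_sequence[1]
  tpp_ee0 <- peep0 - pes_ee0
  tpp_ei0 <- peep0 + vt_l * e_l - pes_ee0

  # population-mean covariate values, for centering the effect modifiers
  vt_pop <- config$vt_ml_per_kg * mean(config$weight_kg) / 1000
  pop <- c(icp = config$baseline_icp_mean, cvp = config$cvp_mean,
           e_rs = config$e_cw_mean + config$e_l_mean,
           tpp_ei = peep0 + vt_pop * config$e_l_mean - config$pes_ee_mean,
           tpp_ee = peep0 - config$pes_ee_mean)
  dev <- c(icp = baseline_icp, cvp = cvp, e_rs = e_rs,
           tpp_ei = tpp_ei0, tpp_ee = tpp_ee0) - pop
  eff <- config$covariate_effects[names(dev)]
  eff[is.na(eff)] <- 0
  slope <- config$icp_peep_slope + sum(eff * dev) +
    stats::rnorm(1, 0, config$icp_peep_slope_sd)

  data.frame(
    animal = animal, sequence = sequence, weight_kg = weight, rr = rr,
    coupling_g = config$coupling_g, icp_peep_slope = slope,
    baseline_icp = baseline_icp, cvp = cvp,
    e_rs = e_rs, e_cw = e_cw, e_l = e_l,
    pes_ee0 = pes_ee0, vt_l = vt_l,
    tpp_ei0 = tpp_ei0, tpp_ee0 = tpp_ee0,
    position_offset = config$position_offset_mmHg,
    stringsAsFactors = FALSE
  )
}

build_animal_design <- function(config, truth) {
  first <- if (truth$sequence == "prone-first") "prone" else "supine"
  second <- if (first == "prone") "supine" else "prone"
  peeps <- config$peep_sequence
  np <- length(peeps)
  per_s <- config$period_minutes * 60
  wash_s <- config$washout_minutes * 60

  label_of <- function(i, p) {
    if (i == 1L && p == peeps[1]) "baseline"
    else if (i == np && p == peeps[1]) "return"
    else "intervention"
  }
  rows <- list()
  t0 <- 0
  for (blk in 1:2) {
    pos <- if (blk == 1L) first else second
    for (i in seq_len(np)) {
      rows[[length(rows) + 1L]] <- data.frame(
        animal = truth$animal, sequence = truth$sequence,
        block = blk, position = pos, period_index = i,
        peep = peeps[i], period_label = label_of(i, peeps[i]),
        start = t0, end = t0 + per_s, stringsAsFactors = FALSE)
      t0 <- t0 + per_s
    }
    if (blk == 1L) {
      rows[[length(rows) + 1L]] <- data.frame(
        animal = truth$animal, sequence = truth$sequence,
        block = blk, position = pos, period_index = np + 1L,
        peep = peeps[1], period_label = "washout",
        start = t0, end = t0 + wash_s, stringsAsFactors = FALSE)
      t0 <- t0 + wash_s
    }
  }
  do.call(rbind, rows)
}

# per-period occlusion-hold measurements consistent with the true elastances:
# Paw_ei - PEEPtot = VT * E_rs and Pes_ei - Pes_ee = VT * E_cw hold exactly
# before noise. Pes_ee rises with PEEP by the chest-wall share E_cw/E_rs.
generate_holds <- function(config, truth, design) {
  vt <- truth$vt_l
  peep0 <- config$peep_sequence[1]
  p <- design$peep
  pes_ee <- truth$pes_ee0 + (truth$e_cw / truth$e_rs) * (p - peep0)
  peeptot <- p
  paw_ei <- peeptot + vt * truth$e_rs
  pes_ei <- pes_ee + vt * truth$e_cw
  rr <- truth$rr
  t_deliver <- (60 / rr) / 3 * 0.8          # I:E 1:2, 20% inspiratory pause
  flow_insp <- vt / t_deliver
  ppeak_rs <- paw_ei + config$airway_resistance * flow_insp
  ppeak_cw <- pes_ei

  hsd <- unname(config$noise_sd["hold"])
  jitter <- function(x) x + noise(length(x), hsd)
  ratio <- 1 + noise(nrow(design), 0.05 * (hsd > 0))
  dpaw <- rep(5, nrow(design))

  out <- data.frame(
    animal = design$animal, block = design$block,
    position = design$position, period_index = design$period_index,
    peep = design$peep, period_label = design$period_label,
    Paw_ei = jitter(paw_ei), PEEPtot = jitter(peeptot),
    Pes_ei = jitter(pes_ei), Pes_ee = jitter(pes_ee),
    Ppeak_rs = jitter(ppeak_rs), Ppeak_cw = jitter(ppeak_cw),
    Paw_ee = jitter(peeptot),
    VT_ml = vt * 1000, RR = rr,
    dPaw = dpaw, dPes = dpaw * ratio,
    stringsAsFactors = FALSE
  )
  # intermittent gas-exchange / hemodynamic period values (descriptive
  # covariates with no built-in effect on the ICP response)
  np <- nrow(design)
  out$PaO2 <- stats::rnorm(1, 188, 25) + noise(np, 5 * (hsd > 0))
  out$PaCO2 <- stats::rnorm(1, 43, 3) + noise(np, 1 * (hsd > 0))
  out$PAP <- stats::rnorm(1, 20, 3) + 0.3 * (p - peep0) / 5 +
    noise(np, 1 * (hsd > 0))
  out$CO <- pmax(1, stats::rnorm(1, 3.8, 0.8) - 0.05 * (p - peep0) / 5 +
                   noise(np, 0.2 * (hsd > 0)))
  out$EVLW <- stats::rnorm(1, 280, 40) + noise(np, 10 * (hsd > 0))
  out$SVV <- pmax(0, stats::rnorm(1, 7, 2) + 0.4 * (p - peep0) / 5 +
                    noise(np, 1 * (hsd > 0)))
  out
}

# single-compartment ventilator model: volume-control square-flow insufflation,
# 20% end-inspiratory pause, passive exponential expiration with time constant
# R / E_rs. Paw = PEEP + E_rs * V + R * Flow(insp); Pes = Pes_ee(PEEP) + E_cw * V.
ventilator_waveforms <- function(t, peep, truth, config) {
  rr <- truth$rr
  tb <- 60 / rr
  u <- (t %% tb) / tb
  vt <- truth$vt_l
  f_del <- 1 / 3 * 0.8
  f_pause_end <- 1 / 3
  tau <- config$airway_resistance / truth$e_rs

  flow <- numeric(length(t))
  vol <- numeric(length(t))
  del <- u < f_del
  pause <- !del & u < f_pause_end
  expn <- u >= f_pause_end

  q_in <- vt / (f_del * tb)
  flow[del] <- q_in
  vol[del] <- vt * u[del] / f_del
  vol[pause] <- vt
  te <- (u[expn] - f_pause_end) * tb
  vol[expn] <- vt * exp(-te / tau)
  flow[expn] <- -vt / tau * exp(-te / tau)

  peep0 <- config$peep_sequence[1]
  pes_ee <- truth$pes_ee0 + (truth$e_cw / truth$e_rs) * (peep - peep0)
  paw <- peep + truth$e_rs * vol + config$airway_resistance * pmax(flow, 0)
  pes <- pes_ee + truth$e_cw * vol
  list(paw = paw, pes = pes, flow = flow, volume = vol)
}
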